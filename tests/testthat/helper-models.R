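# Small hand-built fixtures shared across test files.

# linear chain: A uptake -> conversion -> biomass drain, capacity 10
chainModel <- function() {
  MetabolicModel("chain", data.frame(
    id = c("EX_a", "T1", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c ->"),
    gpr = c(NA, "g1 and g2", NA),
    stringsAsFactors = FALSE), objective = "BIO")
}

chainMedium <- function(cap = -10)
  Medium(data.frame(exchange_id = "EX_a", lb = cap, ub = 1000))

# two parallel routes with yields 1 (R1) and 0.5 (R2)
parallelModel <- function() {
  MetabolicModel("parallel", data.frame(
    id = c("EX_a", "R1", "R2", "BIO"),
    equation = c("a_e <=>", "a_e -> b_c", "2 a_e -> b_c", "b_c ->"),
    gpr = c(NA, "g1", "g2", NA),
    stringsAsFactors = FALSE), objective = "BIO")
}

# equal-yield parallel routes (for pFBA / GIMME rerouting)
equalRoutesModel <- function() {
  MetabolicModel("equal", data.frame(
    id = c("EX_a", "R1", "R2", "BIO"),
    equation = c("a_e <=>", "a_e -> b_c", "a_e -> b_c", "b_c ->"),
    gpr = c(NA, "g1", "g2", NA),
    stringsAsFactors = FALSE), objective = "BIO")
}
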