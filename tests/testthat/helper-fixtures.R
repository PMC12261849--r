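# Fixtures are built in code; nothing is read from disk.

# Six-record toy set: one violation each of rules i, ii, iv (products),
# iv (solvents), v, plus one clean record.
toyRecords <- function() {
  data.frame(
    id = paste0("r", 1:6),
    reactants = c("CCO", "CCO", "CCO", "CCO", "CCO", "CCO"),
    products = c("CC=O", "", "CC=O;CCOC", "CC=O", "CC=O", "CC=O"),
    reagents = c("ox", "ox", "ox", "ox", "ox", "ox"),
    solvents = c("water", "water", "water", "w1;w2;w3", "water", "water"),
    temperatures = c("25", "25", "25", "25", "10;15", "25"),
    yield = c(NA, 0.5, 0.5, 0.5, 0.5, 0.8),
    stringsAsFactors = FALSE)
}

randomRecords <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = paste0("x", seq_len(n)),
    reactants = ifelse(runif(n) < 0.9, "CCO", ""),
    products = ifelse(runif(n) < 0.85, "CC=O",
                      ifelse(runif(n) < 0.5, "CC=O;CCC", "")),
    reagents = replicate(n, paste(sample(c("ox", "cat", "lg", "b1", "b2"),
                                         sample(0:5, 1)), collapse = ";")),
    solvents = replicate(n, paste(sample(c("w", "thf", "dmf"),
                                         sample(0:3, 1)), collapse = ";")),
    temperatures = replicate(n, paste(round(runif(sample(1:3, 1), -10, 190)),
                                      collapse = ";")),
    yield = ifelse(runif(n) < 0.9, round(runif(n), 3), NA),
    stringsAsFactors = FALSE)
}

randomQubo <- function(n, seed, nTerms = 2 * n, vScale = 1) {
  set.seed(seed)
  QuboMatrix(n, i = sample(n, nTerms, replace = TRUE),
             j = sample(n, nTerms, replace = TRUE),
             v = stats::rnorm(nTerms, sd = vScale),
             offset = stats::rnorm(1))
}

# Independent SSE oracle for the binary-coded least-squares expansion:
# evaluates predictions by positional base-2 decoding of each term's bit
# chunk, never through the QUBO machinery.
directSSE <- function(assignBits, data, yields, table, scale = 1000) {
  w <- table@width
  half <- 2^(w - 1)
  tt <- termTable(table)
  vals <- vapply(seq_len(nrow(tt)), function(t) {
    chunk <- assignBits[seq.int(tt$start[t], length.out = w)]
    sum(chunk * 2^(0:(w - 1))) - half
  }, numeric(1))
  sse <- 0
  for (r in seq_len(nrow(data))) {
    act <- quboyield:::.activeTerms(data[r, , drop = FALSE], table)
    sse <- sse + (sum(vals[act]) - scale * yields[r])^2
  }
  sse
}

# Small planted grid whose quadratic surface stays strictly inside (0, 1),
# so the clip nonlinearity is inactive and the surface is in-class.
unclippedGridSpec <- function(slots, seed, sigma = 0) {
  hteGridSpec(slots = slots, mu = 0.5, singletonScale = 0.04,
              pairScale = 0.015, sigma = sigma, seed = seed)
}
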