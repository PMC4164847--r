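# Shared fixtures built in code.

# 3 x 3 judgment matrix with a clear dominance order (1 > 2 > 3)
fjm3 <- function() {
  matrix(c(0.5, 1, 1,
           0,   0.5, 1,
           0,   0,   0.5), 3, byrow = TRUE)
}

# its consistent transform as conventionally printed, to 3 decimals
rcm3_printed <- function() {
  matrix(c(0.5,   0.667, 0.833,
           0.333, 0.5,   0.667,
           0.167, 0.333, 0.5), 3, byrow = TRUE)
}

# 5 x 5 judgment matrix of the case study's natural-ecology node (D1..D5)
fjm5 <- function() {
  matrix(c(0.5, 0,   0,   0,   0,
           1,   0.5, 0,   0,   1,
           1,   1,   0.5, 0.5, 1,
           1,   1,   0.5, 0.5, 1,
           1,   0,   0,   0,   0.5), 5, byrow = TRUE)
}

# all complementary 3 x 3 three-scale matrices (27: upper triangle free)
all_fjm3 <- function() {
  out <- list()
  for (a in c(0, 0.5, 1)) for (b in c(0, 0.5, 1)) for (d in c(0, 0.5, 1)) {
    f <- matrix(0.5, 3, 3)
    f[1, 2] <- a; f[2, 1] <- 1 - a
    f[1, 3] <- b; f[3, 1] <- 1 - b
    f[2, 3] <- d; f[3, 2] <- 1 - d
    out[[length(out) + 1L]] <- f
  }
  out
}

# published per-leaf integrated assessment values of the skidding case
# (weight x standard value, as reported to 4 decimals)
printed_integrated <- function() {
  data.frame(
    leaf = paste0("D", 1:39),
    road = c(0.0070, 0.0200, 0.0338, 0.0332, 0.0093,
             0.0341, 0.0422, 0.0595, 0.0261,
             0.0131, 0.0093, 0.0076, 0.0183,
             0, 0, 0,
             0.0306, 0.0292, 0.0023,
             0.0045, 0.0023, 0.0120,
             0.0035, 0.0026, 0.0046, 0.0080,
             0.0012, 0.0010, 0.0040, 0.0023, 0.0019, 0.0005, 0.0035, 0, 0,
             0.0028, 0.0048, 0.0062, 0.0060),
    cableway = c(0.0083, 0.0208, 0.0430, 0.0354, 0.0144,
                 0.0421, 0.0784, 0.0630, 0.0551,
                 0.0144, 0.0132, 0.0160, 0.0202,
                 0.0258, 0.0105, 0.0211,
                 0.0426, 0.0346, 0.0036,
                 0.0052, 0.0034, 0.0120,
                 0.0038, 0.0030, 0.0055, 0.0088,
                 0.0067, 0.0061, 0.0046, 0.0049, 0.0050, 0.0008, 0.0044,
                 0.0005, 0.0005,
                 0.0070, 0.0118, 0.0070, 0.0092),
    stringsAsFactors = FALSE)
}
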