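# Shared in-code fixtures.

# Toy receptor: single-atom residues on a line along x, one per Angstrom
# offset given in `dists`, all at y = z = 0.
toyReceptor <- function(dists, resid = NULL, chain = "A") {
  n <- length(dists)
  data.frame(chain = chain, resno = seq_len(n),
             resid = if (is.null(resid)) rep("ALA", n) else resid,
             elety = "CA", x = dists, y = 0, z = 0)
}

# Random receptor cloud for brute-force contact oracles.
randomReceptor <- function(nRes, atomsPerRes = 3, seed = 1) {
  set.seed(seed)
  data.frame(chain = "A",
             resno = rep(seq_len(nRes), each = atomsPerRes),
             resid = rep(sample(c("ALA", "ASP", "TRP"), nRes, TRUE),
                         each = atomsPerRes),
             elety = "CA",
             x = runif(nRes * atomsPerRes, -10, 10),
             y = runif(nRes * atomsPerRes, -10, 10),
             z = runif(nRes * atomsPerRes, -10, 10))
}

# Brute-force contact oracle: all-pairs distance scan, no vectorized tricks.
bruteForceContacts <- function(lig, receptor, cutoff) {
  hits <- integer()
  for (r in unique(receptor$resno)) {
    at <- receptor[receptor$resno == r, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(at)))
      for (j in seq_len(nrow(lig)))
        dmin <- min(dmin, sqrt(sum((as.numeric(at[i, ]) - lig[j, ])^2)))
    if (dmin <= cutoff) hits <- c(hits, r)
  }
  sort(hits)
}

# Mutagenesis table mirroring the response-loss pattern of the fructose
# receptor study: eight pocket residues below 1% of WT, the rest spared.
exampleMutagenesisTable <- function() {
  lost <- data.frame(
    residue_number = c(99L, 103L, 161L, 165L, 189L, 193L, 354L, 358L),
    residue_name = c("D", "V", "L", "D", "F", "W", "W", "H"),
    relative_response = c(0.004, 0.006, 0.003, 0.002, 0.008, 0.005,
                          0.004, 0.007))
  spared <- data.frame(
    residue_number = c(102L, 157L, 190L, 355L, 440L),
    residue_name = c("S", "T", "A", "G", "I"),
    relative_response = c(0.82, 0.35, 0.61, 0.25, 0.55))
  rbind(lost, spared)
}
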