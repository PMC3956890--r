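# Independent oracles used across tests.

# MI via the entropy identity H(X) + H(Y) - H(X,Y), in bits; a different
# route from the package's direct plug-in summation.
oracleMI <- function(counts) {
  n <- sum(counts)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p <- counts / n
  px <- c(p[1] + p[2], p[3] + p[4])
  py <- c(p[1] + p[3], p[2] + p[4])
  ent(px) + ent(py) - ent(p)
}

# Upper-tail overlap probability by exhaustive enumeration of all draws of
# size |setA| from the universe.
oracleOverlapP <- function(universe, setB, sizeA, observed) {
  draws <- utils::combn(universe, sizeA)
  hits <- apply(draws, 2, function(d) sum(d %in% setB))
  mean(hits >= observed)
}

# Deterministic expression matrix over given binary rows: encodes each row
# so that median-binarization recovers it (rows must have ceiling(n/2) ones).
encodeRows <- function(rows, samples = NULL) {
  n <- ncol(rows)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  offs <- matrix(seq(0.1, 0.8, length.out = n), nrow(rows), n, byrow = TRUE)
  m <- rows + offs
  dimnames(m) <- list(rownames(rows), samples)
  m
}

# Small directed network from parallel modulator/target vectors.
makeNet <- function(mod, tgt, cmi = NULL, p = NULL) {
  k <- length(mod)
  buildNetwork(data.frame(
    modulator = mod, target = tgt,
    cmi = if (is.null(cmi)) rep(0.5, k) else cmi,
    p_value = if (is.null(p)) rep(0.01, k) else p))
}

# Network on exactly length(outDeg) nodes where node i has out-degree
# outDeg[i]: edges go to the next outDeg[i] nodes in cyclic order, so no
# self-loops or duplicate ordered pairs (requires outDeg[i] <= n - 1).
netWithOutDegrees <- function(outDeg) {
  n <- length(outDeg)
  stopifnot(all(outDeg <= n - 1))
  ids <- sprintf("n%02d", seq_len(n))
  mod <- character(); tgt <- character()
  for (i in seq_len(n)) {
    if (outDeg[i] == 0) next
    to <- ((i - 1 + seq_len(outDeg[i])) %% n) + 1
    mod <- c(mod, rep(ids[i], outDeg[i])); tgt <- c(tgt, ids[to])
  }
  pairs <- data.frame(modulator = mod, target = tgt,
                      cmi = rep(0.5, length(mod)),
                      p_value = rep(0.01, length(mod)))
  net <- buildNetwork(pairs)
  # isolated nodes must still be in the node set
  new("DependencyNetwork", edges = networkEdges(net), nodes = ids)
}
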