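# small hand-built networks used across test files

# feeder P bifurcates into a,b; a,b conflue into c (diamond)
diamondNetwork <- function(lenP = 100, lenA = 80, lenB = 140, lenC = 30) {
  seg <- data.frame(id = c("P", "a", "b", "c"),
                    length_um = c(lenP, lenA, lenB, lenC),
                    diameter_um = c(9, 4.5, 4.2, 5.5),
                    stringsAsFactors = FALSE)
  jn <- data.frame(junction_id = c("J1", "J2"),
                   kind = c("BIFURCATION", "CONFLUENCE"),
                   major_id = c("P", "c"),
                   minor1_id = c("a", "a"),
                   minor2_id = c("b", "b"),
                   stringsAsFactors = FALSE)
  buildNetwork(seg, jn)
}

# feeder followed by a chain of n bifurcations (always descending the first
# daughter); returns the network and the id of the deepest segment
chainNetwork <- function(nBif = 8) {
  ids <- c("P", paste0("s", seq_len(2 * nBif)))
  seg <- data.frame(id = ids, length_um = 50,
                    diameter_um = c(9, rep(4, 2 * nBif)),
                    stringsAsFactors = FALSE)
  jn <- do.call(rbind, lapply(seq_len(nBif), function(k) {
    parent <- if (k == 1) "P" else paste0("s", 2 * (k - 1) - 1)
    data.frame(junction_id = paste0("J", k), kind = "BIFURCATION",
               major_id = parent, minor1_id = paste0("s", 2 * k - 1),
               minor2_id = paste0("s", 2 * k), stringsAsFactors = FALSE)
  }))
  list(net = buildNetwork(seg, jn), tip = paste0("s", 2 * nBif - 1))
}

# uniform-value depth stack
flatStack <- function(value = 10, n = 5, dim = 6,
                      labels = seq(110, by = 20, length.out = n)) {
  DepthStack(replicate(n, matrix(value, dim, dim), simplify = FALSE), labels)
}
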