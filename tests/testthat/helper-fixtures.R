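# shared fixtures, built in code

# independent breadth-first search, used as the oracle for adjacency_order
bfs_orders <- function(neighbours, start) {
  n <- length(neighbours)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(neighbours[frontier])), which(!is.na(dist)))
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1L]] + 1L
    frontier <- nxt
  }
  dist
}

# random symmetric contiguity graph on n nodes
random_graph <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a <- a + t(a)
  structure(list(n = n, area_ids = as.character(seq_len(n)),
                 neighbours = lapply(seq_len(n), function(i) which(a[i, ] > 0))),
            class = "contiguity_graph")
}

# small chain lattice (1 x k)
chain_lattice <- function(k) grid_lattice(1L, k)

# quick fit settings for tests
test_bym_config <- function(...) {
  bym_config(chains = 2L, iter = 2000L, burnin = 1000L, thin = 2L, ...)
}
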