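# Internal helpers.

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards; all package randomness flows through this
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(code)
}

# normal truncated at zero (amplitudes are non-negative), inverse-CDF sampling
rtrunc_norm0 <- function(n, mean, sd) {
  if (sd <= 0) return(pmax(rep(mean, n), 0))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

# union-find over parcel nodes for a set of suprathreshold edges; returns the
# size (edge count) of each connected component and the component id per edge
edge_components <- function(ei, ej) {
  if (length(ei) == 0)
    return(list(edge_comp = integer(0), sizes = integer(0)))
  nodes <- sort(unique(c(ei, ej)))
  idx_i <- match(ei, nodes)
  idx_j <- match(ej, nodes)
  parent <- seq_along(nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(idx_i)) {
    ra <- find(idx_i[k]); rb <- find(idx_j[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp_of_node <- match(roots, unique(roots))
  edge_comp <- comp_of_node[idx_i]
  sizes <- tabulate(edge_comp)
  list(edge_comp = edge_comp, sizes = sizes)
}
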