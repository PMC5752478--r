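# shared fixtures and independent oracles (kept free of package internals so
# they can stand as cross-checks of the implementation)

make_om <- function(values, layer = "mirna") {
  values <- as.matrix(values)
  rownames(values) <- sprintf("f%d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  omics_matrix(values, layer = layer)
}

make_meta <- function(n_per_group, groups = c("a", "b")) {
  sample_metadata(sprintf("s%d", seq_len(n_per_group * length(groups))),
                  rep(groups, each = n_per_group))
}

# exhaustive hypergeometric tail: enumerate every size-n draw from a universe
# of N items of which K are marked, and count draws with >= x marked
hyper_tail_enum <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= x)
}

# literal step-up Benjamini-Hochberg: q_(i) = min_{j>=i} m p_(j) / j, capped
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i, 1)
    q[o[i]] <- running
  }
  q
}

# small deterministic Ct table builder
make_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], gene = r[[2]], ct = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)))
}
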