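# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths they verify.

# median-of-ratios size factors, written loop-wise from the definition
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  out <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    out[j] <- median(counts[keep, j] / ref)
  }
  out
}

# numeric maximization of the NB log-likelihood over coefficients
oracle_nb_loglik <- function(y, X, offsets, alpha) {
  nll <- function(beta) {
    mu <- exp(pmin(drop(X %*% beta) + offsets, 30))
    -sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  start <- qr.solve(X, log(pmax(y, 0.5)) - offsets)
  if (length(start) == 1) {
    o <- optimize(function(b) nll(b), interval = start + c(-5, 5),
                  tol = 1e-12)
    return(-o$objective)
  }
  o1 <- optim(start, nll, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  o2 <- optim(o1$par, nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  -min(o1$value, o2$value)
}

# per-gene membership-pattern enumeration
oracle_venn <- function(named_sets) {
  genes <- sort(unique(unlist(named_sets)))
  pat <- vapply(genes, function(g) {
    paste(as.integer(vapply(named_sets, function(s) g %in% s, logical(1))),
          collapse = "")
  }, character(1))
  split(genes, pat)
}

# brute-force Mann-Whitney U of x (ties count one half)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# brute-force KS D over the pooled support
oracle_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# asymptotic Kolmogorov tail via its series expansion
oracle_ks_p <- function(d, nx, ny) {
  lam <- sqrt(nx * ny / (nx + ny)) * d
  if (lam == 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))))
}

# normal-approximation MW p with tie correction and continuity correction
oracle_mw_p <- function(x, y) {
  u <- oracle_u(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 == 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

# hypergeometric upper tail from binomial coefficients
oracle_hyper_p <- function(overlap, term_size, universe_size, set_size) {
  kk <- overlap:min(term_size, set_size)
  sum(exp(lchoose(term_size, kk) +
            lchoose(universe_size - term_size, set_size - kk) -
            lchoose(universe_size, set_size)))
}

# BH step-up written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive PAM: best medoid subset by total Euclidean dissimilarity
oracle_pam_best <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    tot <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (tot < best) best <- tot
  }
  best
}

# rank-based AUROC (probability a positive outranks a negative)
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# small valid dataset built in code
toy_dataset <- function(n_genes = 8, conditions = c("WT", "PTEN_KO"),
                        times = c(0L, 300L), replicates = 2, seed = 42) {
  withr::with_seed(seed, {
    samples <- pip3tc::generate_design(conditions = conditions,
                                       times = times,
                                       replicates = replicates)
    counts <- matrix(rpois(n_genes * nrow(samples), 50),
                     nrow = n_genes,
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     samples$sample_id))
    genes <- tibble::tibble(gene_id = rownames(counts),
                            length_bp = sample(500:3000, n_genes))
    pip3tc::pip3_dataset(counts, samples, genes)
  })
}

# profiles with c planted shapes plus noise, for cluster tests.  The shape
# centres are hierarchically separated (as early/late x up/down expression
# programs are), so that every merge forced at k < c is unambiguous and the
# first-contiguous-stable-run rule can recover c.
planted_profiles <- function(c_shapes, genes_per_shape = 40, n_samples = 12,
                             noise_sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(0, 1, length.out = n_samples)
    unit <- function(v) v / sqrt(sum(v^2))
    u1 <- unit(cos(2 * pi * t))
    u2 <- unit(sin(2 * pi * t))
    u3 <- unit(cos(4 * pi * t))
    centres <- switch(as.character(c_shapes),
      "2" = list(3 * u1, -3 * u1),
      "3" = list(3 * u1 + 2 * u2, 3 * u1 - 2 * u2, -3 * u1),
      "4" = list(3 * u1 + 2 * u2, 3 * u1 - 2 * u2,
                 -3 * u1 + 1.2 * u3, -3 * u1 - 1.2 * u3),
      stop("c_shapes must be 2, 3 or 4")
    )
    X <- do.call(rbind, lapply(centres, function(s) {
      matrix(rep(s, genes_per_shape), genes_per_shape, n_samples,
             byrow = TRUE)
    }))
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X))
    rownames(X) <- sprintf("g%04d", seq_len(nrow(X)))
    X
  })
}

# fetch a region's gene vector by membership pattern
region_list <- function(regions, pattern) {
  hit <- regions$genes[regions$pattern == pattern]
  if (length(hit) == 0) character(0) else sort(hit[[1]])
}
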