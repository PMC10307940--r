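# Diploid genotyping: outlier filtering of per-read length estimates and
# a two-component Bayesian Gaussian mixture with a small Dirichlet weight
# concentration, so that a homozygous locus collapses onto one component.

# run code with a locally-set RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lower median: for even cardinality report the lower of the two central
# order statistics, keeping integer allele lengths integral
lower_median <- function(x) {
  s <- sort(x)
  s[floor((length(s) + 1) / 2)]
}

#' Filter outlying per-read length estimates
#'
#' Removes estimates further than `n_sd` standard deviations (sample SD
#' over all inputs) from the mean estimate.  A zero or undefined SD
#' retains everything.
#'
#' @param lengths numeric vector of per-read length estimates
#' @param n_sd the SD multiple (default 2)
#' @return the retained estimates, with attribute `removed` holding the
#'   indices of the removed ones
#' @export
filter_outliers <- function(lengths, n_sd = 2) {
  if (length(lengths) == 0L) stop("at least one estimate required")
  mu <- mean(lengths)
  s <- sd(lengths)
  if (is.na(s) || s == 0) {
    out <- lengths
    attr(out, "removed") <- integer(0)
    return(out)
  }
  keep <- abs(lengths - mu) <= n_sd * s
  out <- lengths[keep]
  attr(out, "removed") <- which(!keep)
  out
}

#' Variational Bayesian Gaussian mixture in one dimension
#'
#' Finite mixture with a Dirichlet prior on the weights (concentration
#' `alpha0`), Gaussian priors on the component means, and a single tied
#' Gamma-distributed precision shared by all components.  Mean-field
#' updates are run from `n_init` random initializations and the solution
#' with the highest mixture log-likelihood (at the variational point
#' estimates) is kept.  A small `alpha0` lets superfluous components lose
#' essentially all their weight, which is what turns a homozygous locus
#' into a single occupied cluster.
#'
#' @param x numeric data (at least 2 distinct values)
#' @param K maximum number of components
#' @param alpha0 Dirichlet weight concentration prior
#' @param n_init number of random initializations
#' @param max_iter maximum variational updates per initialization
#' @param tol convergence tolerance on responsibilities
#' @param seed RNG seed for the initializations (restored afterwards)
#' @return list with `weights`, `means`, `sd`, `resp` (n x K), and
#'   `assignment` (argmax responsibility per observation)
#' @export
bayes_gmm_1d <- function(x, K = 2L, alpha0 = 0.25, n_init = 5L,
                         max_iter = 1000L, tol = 1e-7, seed = 1L) {
  n <- length(x)
  stopifnot(n >= 2L, K >= 1L)
  m0 <- mean(x)
  v0 <- max(var(x), 1e-8)
  beta0 <- 1e-2
  a0 <- 1
  b0 <- v0

  run_one <- function() {
    centers <- sample(x, K) + rnorm(K, 0, sqrt(v0) * 1e-3)
    d <- abs(outer(x, centers, "-"))
    hard <- max.col(-d, ties.method = "first")
    r <- matrix(1e-10, n, K)
    r[cbind(seq_len(n), hard)] <- 1
    r <- r / rowSums(r)
    ll <- -Inf
    for (iter in seq_len(max_iter)) {
      Nk <- pmax(colSums(r), 1e-10)
      xbar <- colSums(r * x) / Nk
      Sk <- colSums(r * (outer(x, xbar, "-")^2)) / Nk
      alpha_k <- alpha0 + Nk
      beta_k <- beta0 + Nk
      m_k <- (beta0 * m0 + Nk * xbar) / beta_k
      a <- a0 + n / 2
      b <- b0 + 0.5 * sum(Nk * Sk + (beta0 * Nk / beta_k) * (xbar - m0)^2)
      e_lambda <- a / b
      e_loglambda <- digamma(a) - log(b)
      logw <- digamma(alpha_k) - digamma(sum(alpha_k))
      logrho <- outer(rep(1, n), logw) + 0.5 * e_loglambda -
        0.5 * log(2 * pi) -
        0.5 * (e_lambda * outer(x, m_k, "-")^2 +
                 outer(rep(1, n), 1 / beta_k))
      mx <- apply(logrho, 1, max)
      r_new <- exp(logrho - mx)
      r_new <- r_new / rowSums(r_new)
      delta <- max(abs(r_new - r))
      r <- r_new
      if (delta < tol) break
    }
    w <- alpha_k / sum(alpha_k)
    sdv <- sqrt(b / a)
    dens <- sapply(seq_len(K), function(k) w[k] * dnorm(x, m_k[k], sdv))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
    ll <- sum(log(pmax(rowSums(dens), 1e-300)))
    list(weights = w, means = m_k, sd = sdv, resp = r,
         assignment = max.col(r, ties.method = "first"), loglik = ll)
  }

  with_local_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- run_one()
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  })
}

#' Configuration of the genotyper
#'
#' @param min_reads minimum retained reads required for a call
#' @param outlier_sd SD multiple for [filter_outliers()]
#' @param homozygous_frac a locus is homozygous when the smaller cluster
#'   does not exceed this fraction of the reads
#' @param frac_denominator `"unfiltered"` (fraction of all reads entering
#'   the genotyper, the literal reading) or `"filtered"` (fraction of the
#'   reads surviving outlier removal)
#' @param alpha0,n_init,max_iter Bayesian-GMM settings (tied covariance,
#'   weight concentration prior 0.25, 5 initializations, 1000 iterations)
#' @param seed RNG seed for the mixture initializations
#' @return list of class `genotype_config`
#' @export
genotype_config <- function(min_reads = 3L, outlier_sd = 2,
                            homozygous_frac = 0.20,
                            frac_denominator = c("unfiltered", "filtered"),
                            alpha0 = 0.25, n_init = 5L, max_iter = 1000L,
                            seed = 1L) {
  structure(
    list(min_reads = as.integer(min_reads), outlier_sd = outlier_sd,
         homozygous_frac = homozygous_frac,
         frac_denominator = match.arg(frac_denominator),
         alpha0 = alpha0, n_init = as.integer(n_init),
         max_iter = as.integer(max_iter), seed = seed),
    class = "genotype_config"
  )
}

#' Call a diploid genotype from per-read length estimates
#'
#' Removes outliers beyond `outlier_sd` standard deviations of the mean,
#' fits the two-component Bayesian Gaussian mixture, and applies the
#' zygosity rule: if the smaller cluster does not exceed
#' `homozygous_frac` of the reads, the locus is homozygous and the median
#' retained length is reported; otherwise it is heterozygous and the two
#' cluster medians are reported (sorted ascending).  Medians of even-sized
#' integer sets take the lower central value.
#'
#' @param lengths integer per-read length estimates for one locus
#' @param config a `genotype_config`
#' @return an object of class `genotype_call`: zygosity, allele lengths,
#'   per-read cluster labels, cluster counts, and the filtered read
#'   indices; or a no-call (`zygosity = "none"`) with a reason
#' @export
genotype_call <- function(lengths, config = genotype_config()) {
  n_total <- length(lengths)
  if (n_total == 0L) {
    return(structure(list(zygosity = "none", alleles = integer(0),
                          reason = "no reads", n_total = 0L),
                     class = "genotype_call"))
  }
  retained <- filter_outliers(lengths, n_sd = config$outlier_sd)
  removed <- attr(retained, "removed")
  retained <- as.vector(retained)
  if (length(retained) < config$min_reads) {
    return(structure(
      list(zygosity = "none", alleles = integer(0),
           reason = paste0("only ", length(retained),
                           " reads after filtering (< ",
                           config$min_reads, ")"),
           n_total = n_total, filtered = removed),
      class = "genotype_call"
    ))
  }
  denom <- if (config$frac_denominator == "unfiltered") n_total
           else length(retained)

  if (length(unique(retained)) == 1L) {
    assignment <- rep(1L, length(retained))
    sizes <- c(length(retained), 0L)
    fit <- NULL
  } else {
    fit <- bayes_gmm_1d(retained, K = 2L, alpha0 = config$alpha0,
                        n_init = config$n_init,
                        max_iter = config$max_iter, seed = config$seed)
    assignment <- fit$assignment
    sizes <- tabulate(assignment, nbins = 2L)
  }
  smaller <- min(sizes)
  if (smaller <= config$homozygous_frac * denom) {
    call <- list(zygosity = "homozygous",
                 alleles = as.integer(lower_median(retained)))
  } else {
    med <- sort(vapply(1:2, function(k)
      as.integer(lower_median(retained[assignment == k])), 0L))
    if (med[1] == med[2]) {
      call <- list(zygosity = "homozygous", alleles = med[1])
    } else {
      call <- list(zygosity = "heterozygous", alleles = med)
    }
  }
  structure(
    c(call,
      list(cluster_sizes = sizes, assignment = assignment,
           retained = retained, filtered = removed, n_total = n_total,
           fit = fit)),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$zygosity == "none") {
    cat("<genotype_call> no call: ", x$reason, "\n", sep = "")
  } else {
    cat("<genotype_call> ", x$zygosity, "; allele length",
        if (length(x$alleles) > 1) "s", " ",
        paste(x$alleles, collapse = " / "), " (",
        length(x$retained), "/", x$n_total, " reads retained)\n", sep = "")
  }
  invisible(x)
}
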