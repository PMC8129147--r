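#' Cluster variant-specific causal estimates into mechanisms
#'
#' Fits, by EM, a mixture over the Wald ratios `theta_j` with three kinds of
#' components: `K` substantive clusters, each `Normal(theta_k, se_theta_j^2)`
#' (shared mean, variant-specific variance); a null cluster
#' `Normal(0, se_theta_j^2)`; and a junk cluster, uniform over the observed
#' ratio range extended by twice its width on each side, which absorbs
#' estimates fitting neither a substantive nor the null component. Cluster
#' means are updated as responsibility-weighted precision-weighted means;
#' mixing proportions as mean responsibilities. The best of `n_restarts`
#' seeded initializations (means spread over the observed ratios,
#' k-means++-style) is kept for each `K`, and `K` is selected across
#' `0..k_max` by lowest BIC. The null and junk components are always
#' present, including at `K = 0`.
#'
#' Reporting is conservative: a variant is assigned to a substantive
#' cluster only when its conditional assignment probability is at least
#' `prob_min`, and a cluster is reported only when at least `min_variants`
#' variants satisfy that criterion (see [apply_reporting_rule()], run
#' automatically with its defaults).
#'
#' @param r An `mr_ratios` object with at least 2 variants.
#' @param k_max Maximum number of substantive clusters (default 5).
#' @param n_restarts EM restarts per `K` (default 20).
#' @param seed RNG seed governing all restarts.
#' @param max_iter EM iteration cap per restart (default 500);
#'   convergence when the log-likelihood gain drops below `tol`.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return An `mr_clust_fit` with elements `K`, `means` (tibble
#'   `cluster`, `theta`, `se`, `n_assigned`), `pi`, `responsibilities`
#'   (variants by components), `assignments` tibble (`snp`, `theta`,
#'   `se_theta`, `cluster`, `probability`, `label`), `reported_clusters`,
#'   and `diagnostics` (log-likelihood, BIC path, iterations, restarts,
#'   seed, per-iteration log-likelihood trace of the winning fit).
#' @export
fit_clusters <- function(r, k_max = 5, n_restarts = 20, seed = 1,
                         max_iter = 500, tol = 1e-6) {
  J <- nrow(r)
  if (J < 2) {
    abort("clustering requires at least 2 variants",
          class = "mrsuite_insufficient_error")
  }
  stopifnot(k_max >= 0)
  theta <- r$theta
  se <- r$se_theta
  rng <- range(theta)
  width <- rng[2] - rng[1]
  if (width == 0) width <- 4 * max(se)  # degenerate spread; junk support stays proper
  junk_lo <- rng[1] - 2 * width
  junk_hi <- rng[2] + 2 * width
  log_junk <- -log(junk_hi - junk_lo)

  set.seed(seed)
  fits <- vector("list", k_max + 1)
  for (K in 0:k_max) {
    best <- NULL
    restarts <- if (K == 0) 1 else n_restarts
    for (rep in seq_len(restarts)) {
      # first restart from k-means centers (deterministic, finds well-
      # separated groups); the rest from k-means++-style random spreads
      init <- if (K == 0) {
        numeric(0)
      } else if (rep == 1 && length(unique(theta)) > K) {
        as.numeric(tryCatch(stats::kmeans(theta, centers = K, nstart = 5)$centers,
                            error = function(c) kpp_init(theta, K)))
      } else if (rep == 2) {
        # substantive clusters sit away from the null at zero: seed means
        # at the K ratios most distant from zero
        theta[order(-abs(theta))][seq_len(K)]
      } else {
        kpp_init(theta, K)
      }
      fit <- em_mixture(theta, se, init, log_junk, junk_lo, junk_hi,
                        max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best$K <- K
    best$bic <- -2 * best$loglik + (2 * K + 1) * log(J)
    fits[[K + 1]] <- best
  }
  bic_path <- vapply(fits, function(f) f$bic, numeric(1))
  converged <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(converged)) {
    abort("EM failed to converge for every candidate K",
          class = "mrsuite_em_error",
          best_partial = fits[[which.min(bic_path)]])
  }
  best <- fits[[which.min(ifelse(converged, bic_path, Inf))]]
  model <- build_cluster_model(best, r, bic_path, n_restarts, seed)
  apply_reporting_rule(model)
}

# k-means++-style spread of initial means over the observed ratios
kpp_init <- function(theta, K) {
  means <- numeric(K)
  means[1] <- theta[sample.int(length(theta), 1)]
  if (K > 1) {
    for (k in 2:K) {
      d2 <- vapply(theta, function(t) min((t - means[1:(k - 1)])^2), numeric(1))
      p <- if (sum(d2) > 0) d2 / sum(d2) else NULL
      means[k] <- theta[sample.int(length(theta), 1, prob = p)]
    }
  }
  means
}

em_mixture <- function(theta, se, means, log_junk, junk_lo, junk_hi,
                       max_iter, tol) {
  J <- length(theta)
  K <- length(means)
  C <- K + 2  # components: clusters, null, junk
  pi_c <- rep(1 / C, C)
  w <- 1 / se^2
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE

  log_dens <- function(means) {
    ld <- matrix(0, J, C)
    if (K > 0) {
      for (k in seq_len(K)) ld[, k] <- dnorm(theta, means[k], se, log = TRUE)
    }
    ld[, K + 1] <- dnorm(theta, 0, se, log = TRUE)
    ld[, K + 2] <- ifelse(theta >= junk_lo & theta <= junk_hi, log_junk, -Inf)
    ld
  }

  for (iter in seq_len(max_iter)) {
    ld <- sweep(log_dens(means), 2, log(pi_c), "+")
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    resp <- exp(ld - lse)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && iter > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (K > 0) {
      for (k in seq_len(K)) {
        denom <- sum(resp[, k] * w)
        if (denom > 0) means[k] <- sum(resp[, k] * w * theta) / denom
      }
    }
    pi_c <- colMeans(resp)
    pi_c <- pmax(pi_c, 1e-12)
    pi_c <- pi_c / sum(pi_c)
  }
  mean_se <- if (K > 0) {
    vapply(seq_len(K), function(k) 1 / sqrt(sum(resp[, k] * w)), numeric(1))
  } else numeric(0)
  list(means = means, mean_se = mean_se, pi = pi_c, resp = resp,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       iters = length(ll_trace), converged = converged)
}

build_cluster_model <- function(fit, r, bic_path, n_restarts, seed) {
  K <- fit$K
  comp_names <- c(if (K > 0) paste0("cluster_", seq_len(K)), "null", "junk")
  resp <- fit$resp
  colnames(resp) <- comp_names
  hard <- comp_names[max.col(resp, ties.method = "first")]
  prob <- resp[cbind(seq_len(nrow(resp)), max.col(resp, ties.method = "first"))]
  assignments <- tibble(
    snp = r$snp, theta = r$theta, se_theta = r$se_theta,
    cluster = hard, probability = prob, label = hard
  )
  means <- tibble(
    cluster = if (K > 0) paste0("cluster_", seq_len(K)) else character(0),
    theta = fit$means, se = fit$mean_se,
    n_assigned = if (K > 0) {
      vapply(seq_len(K), function(k) sum(hard == paste0("cluster_", k)), integer(1))
    } else integer(0)
  )
  structure(list(
    K = K, means = means, pi = setNames(fit$pi, comp_names),
    responsibilities = resp, assignments = assignments,
    reported_clusters = character(0),
    prob_min = NA_real_, min_variants = NA_integer_,
    diagnostics = list(loglik = fit$loglik, bic = fit$bic,
                       bic_path = bic_path, iters = fit$iters,
                       ll_trace = fit$ll_trace,
                       n_restarts = n_restarts, seed = seed),
    exposure = attr(r, "exposure_name"), outcome = attr(r, "outcome_name")
  ), class = "mr_clust_fit")
}

#' Apply the conservative cluster-reporting rule
#'
#' A substantive cluster is reported only if at least `min_variants`
#' variants have conditional assignment probability for it of at least
#' `prob_min` (boundaries inclusive). Variants not meeting the bar for a
#' reported cluster are relabeled to the null or junk cluster, whichever
#' carries the larger share of their remaining responsibility.
#'
#' @param model An `mr_clust_fit`.
#' @param prob_min Minimum conditional assignment probability (default 0.8).
#' @param min_variants Minimum qualifying variants per reported cluster
#'   (default 4).
#' @return The model with `reported_clusters` and the `label` column of
#'   `assignments` updated.
#' @export
apply_reporting_rule <- function(model, prob_min = 0.8, min_variants = 4) {
  stopifnot(inherits(model, "mr_clust_fit"))
  resp <- model$responsibilities
  subst <- setdiff(colnames(resp), c("null", "junk"))
  qualifies <- function(k) resp[, k] >= prob_min
  reported <- subst[vapply(subst, function(k) sum(qualifies(k)) >= min_variants,
                           logical(1))]
  label <- character(nrow(resp))
  for (j in seq_len(nrow(resp))) {
    best <- colnames(resp)[which.max(resp[j, ])]
    if (best %in% reported && resp[j, best] >= prob_min) {
      label[j] <- best
    } else {
      label[j] <- if (resp[j, "null"] >= resp[j, "junk"]) "null" else "junk"
    }
  }
  model$assignments$label <- label
  model$reported_clusters <- reported
  model$prob_min <- prob_min
  model$min_variants <- min_variants
  model
}

#' @export
print.mr_clust_fit <- function(x, ...) {
  cat(sprintf("<mr_clust_fit> %s -> %s: K = %d (BIC-selected), %d reported cluster(s)\n",
              x$exposure, x$outcome, x$K, length(x$reported_clusters)))
  if (nrow(x$means) > 0) print(x$means)
  invisible(x)
}

#' @export
tidy.mr_clust_fit <- function(x, ...) x$assignments

#' @export
glance.mr_clust_fit <- function(x, ...) {
  tibble(K = x$K, n_reported = length(x$reported_clusters),
         loglik = x$diagnostics$loglik, bic = x$diagnostics$bic,
         iterations = x$diagnostics$iters, seed = x$diagnostics$seed)
}

#' Per-variant scatter table for cluster plots
#'
#' Joins the fitted cluster labels back onto the harmonized effect sizes,
#' with 95% CI half-widths, ready for a scatter of outcome against exposure
#' associations colored by cluster.
#'
#' @param model An `mr_clust_fit`.
#' @param h The `mr_harmonized` set the ratios were computed from.
#' @return Tibble with one row per clustered variant: `snp`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `ci_half_x`, `ci_half_y`, `cluster`
#'   (reported label), `probability`.
#' @export
cluster_scatter_table <- function(model, h) {
  hd <- as_tibble(h)
  a <- model$assignments
  if (!all(a$snp %in% hd$snp)) {
    abort("cluster model and harmonized set do not match",
          class = "mrsuite_consistency_error")
  }
  hd <- hd[match(a$snp, hd$snp), ]
  tibble(
    snp = a$snp,
    beta_x = hd$beta_x, se_x = hd$se_x,
    beta_y = hd$beta_y, se_y = hd$se_y,
    ci_half_x = qnorm(0.975) * hd$se_x,
    ci_half_y = qnorm(0.975) * hd$se_y,
    cluster = a$label, probability = a$probability
  )
}
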