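# Parametric empirical Bayes: hierarchical (group) inference on first-level
# posteriors via Bayesian model reduction, model-space search and averaging.

#' Specification of the hierarchical (second-level) model
#'
#' Describes the between-subject model \eqn{\theta^{(1)}_i = (X_i \otimes W)
#' \theta^{(2)} + \epsilon^{(2)}}: a design matrix over subjects, a
#' within-subject weight matrix (identity by default), priors on the
#' second-level parameters and a random-effect precision component with
#' log-precision hyperparameter gamma.
#'
#' @param X Design matrix (subjects x covariates). A leading constant column
#'   is added if absent and non-constant covariates are mean-centred, so the
#'   constant encodes the group mean.
#' @param params Names of the first-level parameters entering the second
#'   level.
#' @param W Within-subject weight matrix (`length(params)` x effects);
#'   identity by default.
#' @param beta_prior Prior over the second-level parameters (default
#'   N(0, 1) per element).
#' @param gamma_prior Prior over the random-effect log-precision(s)
#'   (default N(0, 16)).
#' @param re_components List of precision-component matrices over `params`
#'   (default: a single identity component).
#' @return A list of class `hierarchical_spec`.
#' @export
hierarchical_spec <- function(X, params, W = NULL, beta_prior = NULL,
                              gamma_prior = NULL, re_components = NULL) {
  X <- make_design(X)
  rk <- qr(X)
  if (rk$rank < ncol(X)) {
    bad <- colnames(X)[rk$pivot[(rk$rank + 1):ncol(X)]]
    stop_dcm("design matrix is rank deficient; collinear columns: %s",
             paste(bad, collapse = ", "))
  }
  params <- as.character(params)
  w <- length(params)
  if (is.null(W)) W <- diag(w)
  W <- as.matrix(W)
  if (nrow(W) != w) stop_dcm("W must have one row per selected parameter")
  beta_names <- as.vector(outer(seq_len(ncol(W)), colnames(X),
                                function(e, cv) paste(cv, e, sep = ":")))
  if (ncol(W) == w) {
    beta_names <- as.vector(outer(params, colnames(X),
                                  function(p, cv) paste(cv, p, sep = ":")))
  }
  if (is.null(beta_prior)) {
    beta_prior <- gaussian_density(setNames(rep(0, ncol(X) * ncol(W)), beta_names), 1)
  } else {
    beta_prior <- align_density(beta_prior, beta_names)
  }
  if (is.null(re_components)) re_components <- list(diag(w))
  if (is.null(gamma_prior)) {
    gamma_prior <- gaussian_density(
      setNames(rep(0, length(re_components)),
               paste0("gamma", seq_along(re_components))), 16)
  }
  structure(list(X = X, params = params, W = W, beta_prior = beta_prior,
                 gamma_prior = gamma_prior, re_components = re_components,
                 beta_names = beta_names),
            class = "hierarchical_spec")
}

## random-effect covariance implied by log-precisions gamma
re_covariance <- function(spec, gamma) {
  P <- Reduce(`+`, Map(function(g, Q) exp(g) * Q, as.list(gamma), spec$re_components))
  inv_sym(P, jitter = 1e-10)
}

## extract (prior, posterior) pair from a subject's fit
subject_densities <- function(s) {
  if (inherits(s, "dcm_fit")) return(list(prior = s$prior, posterior = s$posterior))
  if (is.list(s) && !is.null(s$prior) && !is.null(s$posterior)) {
    return(list(prior = s$prior, posterior = s$posterior))
  }
  stop_dcm("subject results must be dcm_fit objects or lists with prior and posterior")
}

#' Parametric empirical Bayes over subject-level posteriors
#'
#' Fits the hierarchical model: second-level effects `beta` (design matrix
#' times group effects) with Gaussian random effects whose precision is
#' controlled by log-precision hyperparameters `gamma`. Each subject's
#' contribution to the second-level free energy is evaluated with
#' [reduce_model()], replacing that subject's original prior over the
#' selected parameters with the empirical prior implied by `(beta, gamma)` —
#' so only the first-level posteriors, never the data, are revisited.
#' Optimisation alternates a damped Newton step on `beta` (whose gradient
#' and curvature are available in closed form) with a finite-difference
#' Newton step on `gamma`; steps are accepted only if the free energy
#' increases.
#'
#' @param subject_results List of first-level fits ([dcm_fit()] objects, or
#'   lists with `prior` and `posterior` `gaussian_density` elements), all
#'   sharing parameter names.
#' @param spec A [hierarchical_spec()].
#' @param settings A [dcm_settings()] (iteration budget and tolerance are
#'   reused).
#' @return An object of class `dcm_peb`: `beta_posterior`,
#'   `gamma_posterior`, `free_energy`, `trajectory`,
#'   `subject_empirical_priors`, and bookkeeping (`spec`, counts of group
#'   effects).
#' @export
peb_fit <- function(subject_results, spec, settings = dcm_settings()) {
  stopifnot(inherits(spec, "hierarchical_spec"))
  ns <- length(subject_results)
  if (nrow(spec$X) != ns) stop_dcm("rows(X) = %d but %d subjects given", nrow(spec$X), ns)
  subs <- lapply(subject_results, subject_densities)
  nm_full <- subs[[1]]$prior$names
  for (s in subs) {
    if (!setequal(s$prior$names, nm_full)) stop_dcm("subjects must share parameter names")
  }
  subs <- lapply(subs, function(s) list(prior = align_density(s$prior, nm_full),
                                        posterior = align_density(s$posterior, nm_full)))
  sel <- match(spec$params, nm_full)
  if (anyNA(sel)) stop_dcm("second-level parameters missing at first level: %s",
                           paste(spec$params[is.na(match(spec$params, nm_full))], collapse = ", "))
  w <- length(sel)
  q <- ncol(spec$X)
  nb <- q * ncol(spec$W)

  ## subject-level constants
  P0s <- lapply(subs, function(s) inv_sym(s$prior$cov))
  Pqs <- lapply(subs, function(s) inv_sym(s$posterior$cov))

  ## empirical prior for subject i given (beta, gamma)
  emp_prior <- function(i, beta, Sg) {
    pr <- subs[[i]]$prior
    mB <- matrix(beta, ncol(spec$W), q)       # effects x covariates
    mu_sel <- as.numeric(spec$W %*% (mB %*% spec$X[i, ]))
    mean_r <- pr$mean; mean_r[sel] <- mu_sel
    cov_r <- pr$cov
    cov_r[sel, ] <- 0; cov_r[, sel] <- 0
    cov_r[sel, sel] <- Sg
    gaussian_density(mean_r, cov_r, names = pr$names)
  }

  ## data term and its beta-derivatives at (beta, gamma)
  eval_subjects <- function(beta, gamma, want_deriv = FALSE) {
    Sg <- re_covariance(spec, gamma)
    Pg <- inv_sym(Sg)
    total <- 0
    g_beta <- rep(0, nb); H_beta <- matrix(0, nb, nb)
    for (i in seq_len(ns)) {
      rp <- emp_prior(i, beta, Sg)
      red <- tryCatch(reduce_model(subs[[i]]$prior, subs[[i]]$posterior, rp),
                      error = function(e) NULL)
      if (is.null(red)) return(NULL)
      total <- total + red$delta_F
      if (want_deriv) {
        Mi <- kronecker(matrix(spec$X[i, ], 1, q), spec$W)  # w x nb
        dsel <- red$posterior$mean[sel] - rp$mean[sel]
        g_beta <- g_beta + as.numeric(crossprod(Mi, Pg %*% dsel))
        Sp_sel <- red$posterior$cov[sel, sel, drop = FALSE]
        H_beta <- H_beta + crossprod(Mi, (Pg %*% Sp_sel %*% Pg - Pg) %*% Mi)
      }
    }
    list(L = total, g = g_beta, H = symm(H_beta))
  }

  Pb0 <- inv_sym(spec$beta_prior$cov)
  Pg0 <- inv_sym(spec$gamma_prior$cov)
  ngam <- length(spec$gamma_prior$mean)

  ## joint second-level free energy (deterministic in beta, gamma)
  f2 <- function(beta, gamma) {
    ev <- eval_subjects(beta, gamma, want_deriv = TRUE)
    if (is.null(ev)) return(list(F = -Inf))
    db <- beta - spec$beta_prior$mean
    dg <- gamma - spec$gamma_prior$mean
    Hb <- -ev$H + Pb0
    cholHb <- tryCatch(chol(symm(Hb)), error = function(e) NULL)
    if (is.null(cholHb)) return(list(F = -Inf))
    Sb <- chol2inv(cholHb)
    ld_Sb <- -2 * sum(log(diag(cholHb)))
    ## numeric curvature of the data term in gamma
    hstep <- 0.01
    Hg <- matrix(0, ngam, ngam)
    L0 <- ev$L
    for (j in seq_len(ngam)) {
      gp <- gamma; gp[j] <- gp[j] + hstep
      gm <- gamma; gm[j] <- gm[j] - hstep
      Lp <- eval_subjects(beta, gp)$L %||% NA_real_
      Lm <- eval_subjects(beta, gm)$L %||% NA_real_
      Hg[j, j] <- (Lp - 2 * L0 + Lm) / hstep^2
    }
    Hgp <- -Hg + Pg0
    diag(Hgp) <- pmax(diag(Hgp), 1e-8)
    Sgam <- inv_sym(symm(Hgp))
    Fv <- ev$L - 0.5 * sum(db * (Pb0 %*% db)) - 0.5 * logdet(spec$beta_prior$cov) +
      0.5 * ld_Sb -
      0.5 * sum(dg * (Pg0 %*% dg)) - 0.5 * logdet(spec$gamma_prior$cov) +
      0.5 * logdet(Sgam)
    list(F = Fv, Sb = Sb, Sg = Sgam, g = ev$g, H = ev$H, L = ev$L)
  }

  beta <- spec$beta_prior$mean
  gamma <- spec$gamma_prior$mean
  st <- f2(beta, gamma)
  if (!is.finite(st$F)) stop_dcm("second-level free energy undefined at the prior mean")
  trajectory <- st$F
  tau <- settings$lm_init
  run <- 0L
  for (iter in seq_len(min(settings$max_iter, 32))) {
    improved <- FALSE
    ## beta step (damped Newton on the quadratic data term + prior)
    grad <- st$g - Pb0 %*% (beta - spec$beta_prior$mean)
    Hfull <- -st$H + Pb0
    for (try in 1:8) {
      Hd <- Hfull + tau * diag(pmax(diag(Hfull), 1e-12), nb)
      step <- tryCatch(solve(Hd, grad), error = function(e) NULL)
      if (!is.null(step)) {
        cand_beta <- beta + as.numeric(step)
        cand <- f2(cand_beta, gamma)
        if (is.finite(cand$F) && cand$F > st$F) {
          beta <- cand_beta; st <- cand; tau <- tau / 2; improved <- TRUE
          break
        }
      }
      tau <- tau * 8
    }
    ## gamma step (finite-difference Newton, damped)
    hstep <- 0.01
    for (j in seq_len(ngam)) {
      Lp <- eval_subjects(beta, `[<-`(gamma, j, gamma[j] + hstep))$L %||% NA_real_
      Lm <- eval_subjects(beta, `[<-`(gamma, j, gamma[j] - hstep))$L %||% NA_real_
      if (!is.finite(Lp) || !is.finite(Lm)) next
      g1 <- (Lp - Lm) / (2 * hstep) - Pg0[j, j] * (gamma[j] - spec$gamma_prior$mean[j])
      h1 <- -(Lp - 2 * st$L + Lm) / hstep^2 + Pg0[j, j]
      if (h1 <= 0) h1 <- abs(h1) + 1
      dg <- g1 / h1
      dg <- sign(dg) * min(abs(dg), 2)
      cand_gamma <- gamma; cand_gamma[j] <- gamma[j] + dg
      cand <- f2(beta, cand_gamma)
      if (is.finite(cand$F) && cand$F > st$F) {
        gamma <- cand_gamma; st <- cand; improved <- TRUE
      }
    }
    dF <- st$F - trajectory[length(trajectory)]
    trajectory <- c(trajectory, st$F)
    run <- if (abs(dF) < settings$tol_nats) run + 1L else 0L
    if (run >= settings$tol_run) break
    if (!improved && tau > 1e12) break
  }

  Sgfinal <- re_covariance(spec, gamma)
  structure(list(
    beta_posterior = gaussian_density(beta, st$Sb, names = spec$beta_names),
    gamma_posterior = gaussian_density(gamma, st$Sg, names = spec$gamma_prior$names),
    free_energy = st$F, trajectory = trajectory,
    subject_empirical_priors = lapply(seq_len(ns), emp_prior,
                                      beta = beta, Sg = Sgfinal),
    spec = spec,
    n_second_level = nb,
    n_group_effects = nb - ncol(spec$W),
    group_effect_names = spec$beta_names[-seq_len(ncol(spec$W))]),
    class = "dcm_peb")
}

#' @export
print.dcm_peb <- function(x, ...) {
  cat("Parametric empirical Bayes (second level)\n")
  cat(sprintf("  %d second-level parameters (%d group effects over %d covariates)\n",
              x$n_second_level, x$n_group_effects, ncol(x$spec$X) - 1))
  cat(sprintf("  free energy: %.3f nats\n", x$free_energy))
  invisible(x)
}

#' @export
coef.dcm_peb <- function(object, ...) object$beta_posterior$mean

#' @export
summary.dcm_peb <- function(object, level = 0.90, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  mu <- object$beta_posterior$mean
  sdv <- sqrt(pmax(diag(object$beta_posterior$cov), 0))
  data.frame(mean = mu, sd = sdv, lower = mu - z * sdv, upper = mu + z * sdv,
             row.names = object$beta_posterior$names)
}

#' Search the space of second-level models
#'
#' Scores reduced second-level models in which subsets of the group-effect
#' parameters are switched off (prior variance `1e-8`), using
#' [reduce_model()] on the second-level posterior. With at most 16 free
#' group effects all on/off combinations are scored exhaustively; larger
#' spaces are first pruned greedily (backward elimination of the parameter
#' whose removal costs least evidence) down to 16, then enumerated. Model
#' posterior probabilities are softmax-normalised free energies; a
#' parameter's inclusion probability is the summed probability of models
#' containing it.
#'
#' @param peb A fitted [peb_fit()] object.
#' @param candidate_masks Optional list of logical vectors (length =
#'   number of group effects) to score instead of the automatic space.
#' @param exhaustive_limit Largest number of free parameters enumerated
#'   exhaustively (default 16).
#' @return An object of class `dcm_model_space`: `models` (data frame of
#'   masks, free-energy changes and posterior probabilities),
#'   `inclusion_prob`, and the scored reduced posteriors.
#' @export
search_model_space <- function(peb, candidate_masks = NULL, exhaustive_limit = 16) {
  stopifnot(inherits(peb, "dcm_peb"))
  prior <- peb$spec$beta_prior
  post <- peb$beta_posterior
  effect_idx <- which(post$names %in% peb$group_effect_names)
  ne <- length(effect_idx)
  if (ne == 0 && is.null(candidate_masks)) stop_dcm("no group-effect parameters to search")

  score_mask <- function(mask) {
    rp <- prior
    off <- effect_idx[!mask]
    if (length(off)) {
      rp$cov[off, ] <- 0; rp$cov[, off] <- 0
      diag(rp$cov)[off] <- 1e-8
      rp$mean[off] <- 0
    }
    red <- reduce_model(prior, post, rp)
    list(dF = red$delta_F, posterior = red$posterior)
  }

  if (is.null(candidate_masks)) {
    active <- rep(TRUE, ne)
    ## greedy backward pruning to a tractable exhaustive core
    while (sum(active) > exhaustive_limit) {
      on_idx <- which(active)
      dFs <- vapply(on_idx, function(j) {
        m <- active; m[j] <- FALSE
        score_mask(m)$dF
      }, 0)
      active[on_idx[which.max(dFs)]] <- FALSE
    }
    free_idx <- which(active)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(free_idx)))
    candidate_masks <- lapply(seq_len(nrow(combos)), function(r) {
      m <- rep(FALSE, ne)
      m[free_idx] <- as.logical(combos[r, ])
      m
    })
  } else {
    candidate_masks <- lapply(candidate_masks, function(m) {
      m <- as.logical(m)
      if (length(m) != ne) stop_dcm("masks must have length %d", ne)
      m
    })
  }
  if (!length(candidate_masks)) stop_dcm("empty model space")

  scored <- lapply(candidate_masks, score_mask)
  dF <- vapply(scored, `[[`, 0, "dF")
  pp <- exp(dF - max(dF)); pp <- pp / sum(pp)
  inc <- rep(0, ne)
  for (k in seq_along(candidate_masks)) inc <- inc + pp[k] * candidate_masks[[k]]
  names(inc) <- post$names[effect_idx]
  mask_str <- vapply(candidate_masks, function(m) paste(as.integer(m), collapse = ""), "")
  models <- data.frame(mask = mask_str, delta_F = dF, posterior_prob = pp)
  models <- models[order(-models$posterior_prob), ]
  structure(list(models = models, inclusion_prob = inc,
                 masks = candidate_masks,
                 posteriors = lapply(scored, `[[`, "posterior"),
                 probs = pp, effect_names = post$names[effect_idx]),
            class = "dcm_model_space")
}

#' @export
print.dcm_model_space <- function(x, ...) {
  cat(sprintf("Second-level model space: %d models scored\n", nrow(x$models)))
  cat("Top models:\n")
  print(head(x$models, 5), row.names = FALSE)
  cat("Inclusion probabilities:\n")
  print(round(x$inclusion_prob, 3))
  invisible(x)
}

#' Bayesian model average of scored models
#'
#' Moment-matched Gaussian mixture of the reduced posteriors, weighted by
#' model posterior probability: the averaged mean is the
#' probability-weighted mean, and the averaged covariance adds the
#' between-model spread of the means to the within-model covariances.
#'
#' @param x A `dcm_model_space` from [search_model_space()], or a list of
#'   `list(posterior=, prob=)` pairs.
#' @return A `gaussian_density`.
#' @export
bayesian_model_average <- function(x) {
  if (inherits(x, "dcm_model_space")) {
    posts <- x$posteriors; probs <- x$probs
  } else {
    posts <- lapply(x, `[[`, "posterior")
    probs <- vapply(x, `[[`, 0, "prob")
  }
  if (!length(posts)) stop_dcm("no scored models to average")
  probs <- probs / sum(probs)
  nm <- posts[[1]]$names
  mu <- Reduce(`+`, Map(function(p, wt) wt * p$mean, posts, probs))
  Sg <- Reduce(`+`, Map(function(p, wt) {
    d <- p$mean - mu
    wt * (p$cov + outer(d, d))
  }, posts, probs))
  gaussian_density(mu, unname(symm(Sg)), names = nm)
}
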