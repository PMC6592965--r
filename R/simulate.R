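# Synthetic-data generators: every input the pipeline needs, with known
# ground truth. All generators are deterministic given their seed.

## additive complex Gaussian noise on the stacked Re/Im representation;
## Hermitian symmetry holds by construction of the unstacking
add_csd_noise <- function(pred, noise_sd) {
  if (noise_sd == 0) return(pred)
  vec <- stack_csd(pred) + rnorm(n_stacked(pred), sd = noise_sd)
  unstack_csd(vec, pred$freqs, pred$channels)
}

## default moderate noise: 10% of the mean auto-spectral level
default_noise_sd <- function(pred) {
  n <- length(pred$channels)
  0.1 * mean(sapply(seq_len(n), function(i) mean(Re(pred$csd[, i, i]))))
}

#' Simulate single-subject cross-spectral data
#'
#' Generates one subject's observed cross-spectra: the forward model's
#' predicted CSD plus i.i.d. complex Gaussian observation noise on the
#' stacked real/imaginary parts (Hermitian symmetry is preserved by
#' construction).
#'
#' @param model A `dcm_model` (base parameters).
#' @param freqs Frequency grid in Hz (default 4-100 Hz at 1 Hz).
#' @param theta Named log-scaling parameters defining the subject's true
#'   deviation from the base model (default none).
#' @param noise_sd Observation-noise SD on the Re/Im parts; `NULL` (default)
#'   uses 10% of the mean auto-spectral level.
#' @param seed Integer seed.
#' @return List with `data` (`spectral_data`), and `truth` (list holding
#'   `theta`, the effective model, `noise_sd`, `seed`).
#' @export
simulate_subject <- function(model, freqs = seq(4, 100, by = 1), theta = NULL,
                             noise_sd = NULL, seed = 1) {
  m <- if (length(theta)) apply_theta(model, theta) else model
  pred <- predict_csd(m, freqs)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(pred)
  set.seed(as.integer(seed) %% 2147483647)
  data <- add_csd_noise(pred, noise_sd)
  list(data = data,
       truth = list(theta = theta, model = m, noise_sd = noise_sd, seed = seed))
}

#' Simulate a multi-subject cohort with second-level structure
#'
#' Draws each subject's first-level log-scaling parameters from the
#' hierarchical linear model \eqn{\theta_i = \beta^\top X_i + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \mathrm{re\_sd}^2 I)}, then simulates that
#' subject's cross-spectra with [simulate_subject()]. Subjects whose drawn
#' parameters make the forward model unstable are redrawn (up to 10 times).
#'
#' @param n_subjects Number of subjects.
#' @param X Design matrix (subjects x covariates, first column constant);
#'   default a constant-only design.
#' @param beta Second-level effects: a covariates x parameters matrix with
#'   column names naming first-level parameters (rows align with columns of
#'   `X`).
#' @param re_sd Between-subject (random-effect) SD on the log-scaled
#'   parameters.
#' @param model Base `dcm_model` shared by the cohort.
#' @param freqs Frequency grid in Hz.
#' @param noise_sd Observation-noise SD (`NULL` = 10% of mean auto level).
#' @param seed Integer seed.
#' @return List with `subjects` (list of per-subject `data`/`truth` pairs),
#'   `X`, `beta`, `re_sd` and `seed`.
#' @export
simulate_group <- function(n_subjects, X = NULL, beta = NULL, re_sd = 0.1,
                           model = mass_model(), freqs = seq(4, 100, by = 1),
                           noise_sd = NULL, seed = 1) {
  if (is.null(X)) X <- matrix(1, n_subjects, 1, dimnames = list(NULL, "const"))
  X <- as.matrix(X)
  if (nrow(X) != n_subjects) stop_dcm("rows(X) must equal n_subjects")
  if (is.null(beta)) {
    beta <- matrix(0, ncol(X), 0)
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != ncol(X)) stop_dcm("rows(beta) must match cols(X)")
  pnames <- colnames(beta)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    for (attempt in 1:10) {
      set.seed(child_seed(seed, i * 100 + attempt))
      mu_i <- if (ncol(beta)) setNames(as.numeric(crossprod(beta, X[i, ])), pnames) else NULL
      eps <- rnorm(length(mu_i %||% numeric(0)), sd = re_sd)
      extra <- NULL
      if (re_sd > 0 && is.null(mu_i)) {
        ## random effects on all free-able gains when no beta given
        pn <- setdiff(free_param_names(model),
                      c(paste0("kappa", 1:4), "alpha_u", "beta_u", "alpha_n", "beta_n"))
        extra <- setNames(rnorm(length(pn), sd = re_sd), pn)
      }
      theta_i <- if (is.null(mu_i)) extra else setNames(mu_i + eps, pnames)
      sim <- tryCatch(
        simulate_subject(model, freqs, theta = theta_i, noise_sd = noise_sd,
                         seed = child_seed(seed, i)),
        error = function(e) NULL)   # instability or numerical failure: redraw
      if (!is.null(sim)) break
    }
    if (is.null(sim)) stop_dcm("subject %d unstable after 10 redraws", i)
    subjects[[i]] <- sim
  }
  list(subjects = subjects, X = X, beta = beta, re_sd = re_sd, seed = seed)
}

#' Two-channel laminar mass model
#'
#' Builds the four-population mass model used for laminar analyses: the
#' fast pair (populations 1 and 4, short time constants) is read by the
#' superficial channel and the slow pair (populations 2 and 3) by the deep
#' channel, generating a gamma-band superficial peak and a slower
#' (alpha/beta) deep peak. One exogenous input drives both pairs
#' (populations 1 and 3), so the channels share a common drive and their
#' cross-spectrum is the shared-input term. This fast-superficial/slow-deep
#' asymmetry is a synthetic-benchmark convention, not a biological claim.
#'
#' @param sup_params List with `kappa` (rate constant, s^-1) and `gain`
#'   (scaling of the fast-pair gains) for the superficial populations.
#' @param deep_params Same for the deep (slow) populations.
#' @param cross_gain Scaling of the fast-to-slow coupling gains (`a31`,
#'   `a34`); 0 decouples the deep pair from the drive.
#' @return A two-channel `dcm_mass` model with channels `sup` and `deep`.
#' @export
laminar_model <- function(sup_params = list(kappa = 500, gain = 1),
                          deep_params = list(kappa = 100, gain = 1),
                          cross_gain = 1) {
  a <- c(a11 = 1000, a14 = 2000, a23 = 600, a22 = 400, a32 = 600,
         a31 = 400, a33 = 400, a34 = 1500, a41 = 2000, a44 = 1000)
  sup_g <- sup_params$gain %||% 1
  deep_g <- deep_params$gain %||% 1
  a[c("a11", "a14", "a41", "a44")] <- a[c("a11", "a14", "a41", "a44")] * sup_g
  a[c("a22", "a23", "a32", "a33")] <- a[c("a22", "a23", "a32", "a33")] * deep_g
  a[c("a31", "a34")] <- a[c("a31", "a34")] * cross_gain
  mass_model(kappa = c(sup_params$kappa %||% 500, deep_params$kappa %||% 100,
                       deep_params$kappa %||% 100, sup_params$kappa %||% 500),
             a = a,
             Lw = rbind(sup = 2000 * c(1, 0, 0, 1),
                        deep = 2000 * c(0, -1, 1, 0)),
             B_weights = c(1, 0, 1, 0),
             channels = c("sup", "deep"))
}

#' Simulate two-channel laminar spectra
#'
#' Generates superficial/deep channel pairs from the laminar mass model
#' ([laminar_model()]): both channels observe the same four-population
#' source driven by one exogenous input, so their cross-spectrum is the
#' shared-input term \eqn{T_{sup}\, g_u\, T_{deep}^\dagger} (plus the
#' channel-noise floor).
#'
#' @inheritParams laminar_model
#' @param freqs Frequency grid (Hz).
#' @param noise_sd Observation-noise SD (`NULL` = 10% of mean auto level).
#' @param seed Integer seed.
#' @return List with `data` (two-channel `spectral_data`), `model`, and
#'   `truth`.
#' @export
simulate_laminar <- function(sup_params = list(kappa = 500, gain = 1),
                             deep_params = list(kappa = 100, gain = 1),
                             cross_gain = 1, freqs = seq(4, 100, by = 1),
                             noise_sd = NULL, seed = 1) {
  m <- laminar_model(sup_params, deep_params, cross_gain)
  pred <- predict_csd(m, freqs)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(pred)
  set.seed(as.integer(seed) %% 2147483647)
  data <- add_csd_noise(pred, noise_sd)
  list(data = data, model = m,
       truth = list(sup_params = sup_params, deep_params = deep_params,
                    cross_gain = cross_gain, noise_sd = noise_sd, seed = seed))
}

#' Simulate a depth-resolved LFP profile with an injected sink
#'
#' Superposes a smooth, time-gated current-sink signature (a Gaussian
#' depth profile with an alpha-function time course, appearing as a
#' negative-going potential) on temporally correlated (low-pass filtered)
#' noise across a uniformly spaced laminar probe.
#'
#' @param n_contacts Number of contacts (default 24, spacing 100 um).
#' @param sink_contact Contact index at the sink centre.
#' @param onset_ms Sink onset time (ms; times run -50..150 ms, stimulus at
#'   0).
#' @param amplitude Peak sink amplitude (mV).
#' @param noise_sd Noise SD (mV).
#' @param seed Integer seed.
#' @return A `depth_lfp` object.
#' @export
simulate_depth_lfp <- function(n_contacts = 24, sink_contact = 7,
                               onset_ms = 20, amplitude = 1, noise_sd = 0.05,
                               seed = 1) {
  if (sink_contact < 1 || sink_contact > n_contacts) {
    stop_dcm("sink_contact must lie in 1..%d", n_contacts)
  }
  set.seed(as.integer(seed) %% 2147483647)
  times <- seq(-50, 150, by = 1)
  depths <- seq_len(n_contacts) * 100   # um
  tau <- 15
  tt <- pmax(times - onset_ms, 0)
  gate <- (tt / tau) * exp(1 - tt / tau)          # alpha function, peak 1
  prof <- exp(-(seq_len(n_contacts) - sink_contact)^2 / 2)
  signal <- -amplitude * outer(prof, gate)
  ## temporally correlated (low-pass) noise; AR coefficient chosen so that
  ## persistent baseline excursions past the default detection threshold are
  ## rare, as in trial-averaged evoked responses
  noise <- matrix(rnorm(n_contacts * length(times)), n_contacts)
  noise <- t(apply(noise, 1, function(x) as.numeric(stats::filter(x, 0.3, "recursive"))))
  noise <- noise * noise_sd / sd(noise)
  depth_lfp(times, depths, signal + noise)
}
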