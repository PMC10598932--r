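#' Configuration for a synthetic PDO drug screen
#'
#' Describes a simulated screen with the statistical structure the pipeline
#' assumes: each PDO x drug pair follows a three-parameter log-logistic
#' (Hill) dose-response sampled around a per-drug IC50, read out as
#' triplicate luminescence wells plus solvent-control wells on multi-plate
#' layouts (60 usable center wells per 96-well plate), with multiplicative
#' plate-reader noise, occasional deliberately noisy triplicates, and
#' missing drug-PDO pairs.
#'
#' @param n_pdos Number of PDO lines (default 24).
#' @param panel A [drug panel][as_drug_panel] supplying the concentration
#'   axes.
#' @param seed Mandatory integer seed; the generated screen is a pure
#'   function of the configuration including the seed.
#' @param log_ic50_mean Per-drug mean of the latent log10 IC50 (named vector
#'   or single value); defaults to each drug's medium test concentration —
#'   the panel's concentrations were calibrated to straddle the average
#'   IC50.
#' @param log_ic50_sd Between-PDO SD of the latent log10 IC50 (default 0.5).
#' @param hill_slope Hill slope of the response curve (default 1).
#' @param e_inf Residual viability fraction at saturating drug (default 0.1).
#' @param well_cv Coefficient of variation of per-well noise (default 0.08).
#' @param n_replicates Wells per condition (default 3).
#' @param n_controls_per_plate Solvent-control wells per plate (default 6,
#'   filling each 60-well plate as 18 conditions x 3 wells + 6 controls).
#' @param bad_triplicate_rate Fraction of conditions degraded with inflated
#'   replicate spread (default 0.02).
#' @param bad_sem_multiplier Injected SEM of a degraded condition, as a
#'   multiple of `qc_se_threshold` (default 2).
#' @param qc_se_threshold QC threshold the degradation is sized against, in
#'   percent points (default 12).
#' @param missing_pair_rate Fraction of PDO x drug pairs never tested
#'   (default 0.02); spiked pairs are never made missing.
#' @param spiked_pairs Optional data frame (`pdo`, `drug`, `log_ic50_shift`)
#'   of ground-truth sensitive pairs; negative shifts lower the IC50 and
#'   increase sensitivity.
#' @param noise `"gaussian"` (multiplicative, truncated at -1) or
#'   `"lognormal"`.
#' @param control_scale Expected control-well luminescence in RLU (default
#'   10000), jittered per plate to exercise per-plate normalization.
#' @param plate_effect_sd Log-scale SD of the per-plate scale factor
#'   (default 0.05).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pdos = 24, panel = default_panel(), seed,
                       log_ic50_mean = NULL, log_ic50_sd = 0.5,
                       hill_slope = 1, e_inf = 0.1, well_cv = 0.08,
                       n_replicates = 3, n_controls_per_plate = 6,
                       bad_triplicate_rate = 0.02, bad_sem_multiplier = 2,
                       qc_se_threshold = 12, missing_pair_rate = 0.02,
                       spiked_pairs = NULL,
                       noise = c("gaussian", "lognormal"),
                       control_scale = 10000, plate_effect_sd = 0.05) {
  noise <- match.arg(noise)
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a seed is mandatory for reproducibility")
  }
  seed <- as.integer(seed)
  if (is.null(log_ic50_mean)) {
    log_ic50_mean <- stats::setNames(panel$log10M_medium, panel$drug)
  } else if (length(log_ic50_mean) == 1 && is.null(names(log_ic50_mean))) {
    log_ic50_mean <- stats::setNames(rep(log_ic50_mean, nrow(panel)),
                                     panel$drug)
  }
  if (!all(panel$drug %in% names(log_ic50_mean))) {
    stop("log_ic50_mean must cover every panel drug")
  }
  check_rate <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1) {
      stop(nm, " must be in [0, 1)")
    }
  }
  check_rate(bad_triplicate_rate, "bad_triplicate_rate")
  check_rate(missing_pair_rate, "missing_pair_rate")
  check_rate(e_inf, "e_inf")
  if (hill_slope <= 0) stop("hill_slope must be positive")
  if (well_cv < 0) stop("well_cv must be non-negative")
  if (n_pdos < 1 || n_replicates < 1 || n_controls_per_plate < 1) {
    stop("n_pdos, n_replicates and n_controls_per_plate must be >= 1")
  }
  if (!is.null(spiked_pairs)) {
    stopifnot(all(c("pdo", "drug", "log_ic50_shift") %in%
                    names(spiked_pairs)))
  }
  structure(list(n_pdos = n_pdos, panel = panel, seed = seed,
                 log_ic50_mean = log_ic50_mean, log_ic50_sd = log_ic50_sd,
                 hill_slope = hill_slope, e_inf = e_inf, well_cv = well_cv,
                 n_replicates = n_replicates,
                 n_controls_per_plate = n_controls_per_plate,
                 bad_triplicate_rate = bad_triplicate_rate,
                 bad_sem_multiplier = bad_sem_multiplier,
                 qc_se_threshold = qc_se_threshold,
                 missing_pair_rate = missing_pair_rate,
                 spiked_pairs = spiked_pairs, noise = noise,
                 control_scale = control_scale,
                 plate_effect_sd = plate_effect_sd),
            class = "sim_config")
}

#' Expected viability under the log-logistic dose-response model
#'
#' v(c) = 100 * (e_inf + (1 - e_inf) / (1 + 10^(hill * (c - log_ic50)))),
#' the standard three-parameter Hill curve on log10 molar concentration:
#' 100% far below the IC50, 100 * e_inf at saturating drug, 50% at the IC50
#' when e_inf = 0.
#'
#' @param conc_log10M Log10 molar concentration(s).
#' @param log_ic50 Log10 molar IC50.
#' @param hill Hill slope (> 0).
#' @param e_inf Residual viability fraction in `[0, 1)`.
#' @return Expected relative viability in percent, same length as
#'   `conc_log10M`.
#' @examples
#' expected_viability(c(-7, -6.25, -5.5), log_ic50 = -6.25, hill = 1,
#'                    e_inf = 0)  # ~ (84.9, 50.0, 15.1)
#' @export
expected_viability <- function(conc_log10M, log_ic50, hill = 1,
                               e_inf = 0.1) {
  if (hill <= 0) stop("hill must be positive")
  100 * (e_inf + (1 - e_inf) / (1 + 10^(hill * (conc_log10M - log_ic50))))
}

#' Generate a synthetic well-level screen with ground truth
#'
#' Draws a latent log10 IC50 per PDO x drug pair (spiked pairs shifted),
#' evaluates the expected viability triple at the panel concentrations,
#' lays the triplicate wells out on multi-plate 60-center-well layouts with
#' per-plate solvent controls and a per-plate scale factor, and adds
#' multiplicative well noise. Deliberately degraded conditions receive a
#' structured replicate spread whose injected SEM is
#' `bad_sem_multiplier * qc_se_threshold` percent points in expectation, so
#' they should fail the QC rule. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `wells` (validated long-format well data frame) and
#'   `truth` (list with per-pair `params` — latent parameters, expected
#'   viabilities, `spiked`, `missing` flags — and `degraded`, the conditions
#'   given inflated spread).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  pdos <- sprintf("SIM%03d", seq_len(config$n_pdos))
  n_rep <- config$n_replicates

  params <- expand.grid(pdo = pdos, drug = panel$drug,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  params <- params[order(params$pdo, params$drug), ]
  rownames(params) <- NULL
  params$log_ic50 <- config$log_ic50_mean[params$drug] +
    stats::rnorm(nrow(params), 0, config$log_ic50_sd)
  params$hill <- config$hill_slope
  params$e_inf <- config$e_inf
  params$spiked <- FALSE
  if (!is.null(config$spiked_pairs)) {
    sp <- config$spiked_pairs
    i <- match(paste(sp$pdo, sp$drug), paste(params$pdo, params$drug))
    if (anyNA(i)) stop("spiked pair(s) not in the screen grid")
    params$log_ic50[i] <- params$log_ic50[i] + sp$log_ic50_shift
    params$spiked[i] <- TRUE
  }
  params$missing <- stats::runif(nrow(params)) < config$missing_pair_rate &
    !params$spiked

  conc <- as.matrix(panel[, c("log10M_low", "log10M_medium", "log10M_high")])
  rownames(conc) <- panel$drug
  ev <- t(vapply(seq_len(nrow(params)), function(i) {
    expected_viability(conc[params$drug[i], ], params$log_ic50[i],
                       params$hill[i], params$e_inf[i])
  }, numeric(3)))
  params$ev_low <- ev[, 1]
  params$ev_medium <- ev[, 2]
  params$ev_high <- ev[, 3]

  levels <- c("low", "medium", "high")
  noise_factor <- function(n) {
    if (config$well_cv == 0) return(rep(1, n))
    if (config$noise == "gaussian") {
      pmax(1 + stats::rnorm(n, 0, config$well_cv), 0)
    } else {
      sdlog <- sqrt(log(1 + config$well_cv^2))
      exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    }
  }
  # Replicate offset pattern with unit SD: injected SEM (percent points) for
  # a degraded condition is bad_sem_multiplier * qc_se_threshold.
  base_pattern <- seq(-1, 1, length.out = n_rep)
  if (n_rep > 1) base_pattern <- base_pattern / stats::sd(base_pattern)
  injected_sem <- config$bad_sem_multiplier * config$qc_se_threshold
  spread_pct <- injected_sem * sqrt(n_rep)

  conditions_per_plate <- max(1L,
                              (60L - config$n_controls_per_plate) %/% n_rep)
  centers <- center_wells()
  rows <- vector("list", config$n_pdos)
  degraded <- list()

  for (p in seq_along(pdos)) {
    pd <- pdos[p]
    pp <- params[params$pdo == pd & !params$missing, , drop = FALSE]
    cond <- data.frame(drug = rep(pp$drug, each = 3),
                       level = rep(levels, nrow(pp)),
                       ev = as.vector(t(as.matrix(
                         pp[, c("ev_low", "ev_medium", "ev_high")]))),
                       stringsAsFactors = FALSE)
    cond$bad <- stats::runif(nrow(cond)) < config$bad_triplicate_rate
    n_plates <- ceiling(nrow(cond) / conditions_per_plate)
    plate_of <- rep(seq_len(n_plates),
                    each = conditions_per_plate)[seq_len(nrow(cond))]
    plate_scale <- config$control_scale *
      exp(stats::rnorm(n_plates, 0, config$plate_effect_sd))

    out <- vector("list", n_plates)
    for (k in seq_len(n_plates)) {
      ck <- cond[plate_of == k, , drop = FALSE]
      plate_id <- sprintf("%s_P%d", pd, k)
      scale <- plate_scale[k]
      n_cond_wells <- nrow(ck) * n_rep
      lum <- rep(ck$ev, each = n_rep) / 100 * scale *
        noise_factor(n_cond_wells)
      bad_rows <- which(ck$bad)
      for (b in bad_rows) {
        off <- scale * spread_pct / 100 *
          sample(base_pattern)                    # random well assignment
        idx <- (b - 1) * n_rep + seq_len(n_rep)
        lum[idx] <- pmax(lum[idx] + off, 0)
        degraded[[length(degraded) + 1]] <- data.frame(
          pdo = pd, drug = ck$drug[b], level = ck$level[b],
          injected_sem = injected_sem, stringsAsFactors = FALSE)
      }
      ctrl_lum <- scale * noise_factor(config$n_controls_per_plate)
      well_pos <- centers[seq_len(n_cond_wells + config$n_controls_per_plate)]
      out[[k]] <- data.frame(
        plate = plate_id,
        well = well_pos,
        pdo = pd,
        drug = c(rep(ck$drug, each = n_rep),
                 rep("CONTROL", config$n_controls_per_plate)),
        level = c(rep(ck$level, each = n_rep),
                  rep("control", config$n_controls_per_plate)),
        signal = c(lum, ctrl_lum),
        stringsAsFactors = FALSE)
    }
    rows[[p]] <- do.call(rbind, out)
  }
  wells <- do.call(rbind, rows)
  wells$signal <- as.character(wells$signal)
  wells <- validate_wells(wells)
  degraded <- if (length(degraded) > 0) {
    do.call(rbind, degraded)
  } else {
    data.frame(pdo = character(), drug = character(), level = character(),
               injected_sem = numeric(), stringsAsFactors = FALSE)
  }
  list(wells = wells,
       truth = list(params = params, degraded = degraded, config = config))
}

#' Generate matched clinical records from simulation ground truth
#'
#' One clinical record per selected PDO: the drug is the PDO's spiked
#' (ground-truth sensitive) drug when it has one, otherwise its first
#' tested panel drug; the best response is a responder outcome (PR or SD,
#' equiprobable) with probability `p_response_spiked` for spiked pairs and
#' `p_response_other` otherwise, else PD. Deterministic under the seed.
#'
#' @param truth The `truth` element of [simulate_screen()] output.
#' @param p_response_spiked Probability a spiked pair's patient responds.
#' @param p_response_other Probability for non-spiked pairs.
#' @param pdos PDO ids to emit records for (default all).
#' @param seed Integer seed.
#' @return A clinical record data frame (`patient`, `pdo`, `drug`,
#'   `best_response`).
#' @export
generate_clinical <- function(truth, p_response_spiked = 0.9,
                              p_response_other = 0.2, pdos = NULL,
                              seed = truth$config$seed + 1) {
  stopifnot(p_response_spiked >= 0, p_response_spiked <= 1,
            p_response_other >= 0, p_response_other <= 1)
  set.seed(as.integer(seed))
  params <- truth$params
  if (is.null(pdos)) pdos <- unique(params$pdo)
  recs <- lapply(pdos, function(pd) {
    pp <- params[params$pdo == pd & !params$missing, , drop = FALSE]
    if (nrow(pp) == 0) return(NULL)
    i <- if (any(pp$spiked)) which(pp$spiked)[1] else 1L
    p_resp <- if (pp$spiked[i]) p_response_spiked else p_response_other
    responds <- stats::runif(1) < p_resp
    data.frame(patient = sub("^SIM", "PAT", pd), pdo = pd,
               drug = pp$drug[i],
               best_response = if (responds) {
                 sample(c("PR", "SD"), 1)
               } else "PD",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no PDOs with tested pairs to select")
  rownames(out) <- NULL
  out
}
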