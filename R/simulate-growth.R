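#' Ellipsoid tumor volume from caliper measurements
#'
#' \deqn{V = L \times W \times D \times \pi / 6} in cubic millimetres, the
#' modified-ellipsoid formula used for caliper measurements of length,
#' width and depth.
#'
#' @param L,W,D dimensions in mm, all >= 0 (vectorized).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(L, W, D) {
  if (any(c(L, W, D) < 0)) stop("tumor dimensions must be non-negative", call. = FALSE)
  L * W * D * pi / 6
}

#' Simulate tumor-growth trajectories with response labels and survival
#'
#' Generates piecewise-exponential volume trajectories for tumors starting
#' near 100 mm^3 at treatment start. In the treated arm each tumor draws a
#' responder archetype (durable regression / transient regression followed
#' by relapse / sustained growth) with probabilities matching the observed
#' category frequencies (13 DR, 6 SR, 34 NR of 53); the control arm grows
#' throughout. The observed trajectory is then labeled by explicit rules
#' operationalizing the response categories:
#' \itemize{
#'   \item DR: volume never exceeds 1.2x baseline after day 14 and the
#'     final volume is at most baseline;
#'   \item SR: volume shrinks at least 30\% below baseline, then exceeds
#'     baseline before study end;
#'   \item NR: otherwise.
#' }
#' Survival time is the first measurement day on which volume reaches the
#' 1,500 mm^3 burden endpoint (event), otherwise the record is censored at
#' study end; a small independent-sacrifice hazard produces additional
#' censoring.
#'
#' @param n_treated,n_control tumors per arm.
#' @param study_days trial length in days.
#' @param measure_every caliper measurement interval (days).
#' @param p_dr,p_sr archetype probabilities in the treated arm (remainder
#'   grows). Defaults 13/53 and 6/53.
#' @param sacrifice_rate daily probability of censoring independent of
#'   tumor growth.
#' @param seed integer seed.
#' @return list with \code{growth} (long data frame: \code{tumor_id},
#'   \code{day}, \code{L}, \code{W}, \code{D}, \code{volume}, \code{arm},
#'   \code{response_category}) and \code{survival} (one row per tumor:
#'   \code{subject_id}, \code{time}, \code{event}, \code{group}).
#' @export
simulate_growth_and_label <- function(n_treated = 53L, n_control = 19L,
                                      study_days = 90L, measure_every = 3L,
                                      p_dr = 13 / 53, p_sr = 6 / 53,
                                      sacrifice_rate = 0.002, seed = 1L) {
  stopifnot(p_dr + p_sr <= 1, n_treated + n_control >= 1L)
  days <- seq(0L, study_days, by = measure_every)
  arms <- rep(c("anti-PD-1", "IgG"), c(n_treated, n_control))

  traj <- with_seed(derive_seed(seed, "growth"), {
    lapply(seq_along(arms), function(i) {
      arche <- if (arms[i] == "anti-PD-1") {
        sample(c("regress", "relapse", "grow"), 1L,
               prob = c(p_dr, p_sr, 1 - p_dr - p_sr))
      } else "grow"
      v0 <- stats::rlnorm(1L, log(100), 0.15)
      noise <- stats::rnorm(length(days), 0, 0.04)
      rate <- switch(arche,
        grow = rep(stats::rlnorm(1L, log(0.06), 0.25), length(days)),
        regress = rep(-stats::rlnorm(1L, log(0.05), 0.25), length(days)),
        relapse = {
          t_rel <- stats::runif(1L, 20, 45)
          ifelse(days < t_rel, -stats::rlnorm(1L, log(0.06), 0.25),
                 stats::rlnorm(1L, log(0.08), 0.25))
        })
      logv <- log(v0) + cumsum(c(0, rate[-1L] * diff(days))) + noise
      pmax(exp(logv), 0.5)
    })
  })

  label_one <- function(vol, day) {
    baseline <- vol[1L]
    after14 <- vol[day >= 14L]
    if (all(after14 <= 1.2 * baseline) && vol[length(vol)] <= baseline) return("DR")
    if (any(vol < 0.7 * baseline) && any(vol[which.min(vol):length(vol)] > baseline))
      return("SR")
    "NR"
  }

  sac <- with_seed(derive_seed(seed, "sacrifice"),
                   stats::rgeom(length(arms), sacrifice_rate) + 1L)

  growth <- vector("list", length(arms))
  surv <- vector("list", length(arms))
  for (i in seq_along(arms)) {
    vol <- traj[[i]]
    hit <- which(vol >= 1500)
    end_idx <- if (length(hit)) hit[1L] else length(days)
    # independent sacrifice censors before the endpoint is reached
    sac_idx <- which(days >= sac[i])
    censored_early <- length(sac_idx) > 0 && sac_idx[1L] < end_idx
    last_idx <- if (censored_early) sac_idx[1L] else end_idx
    keep <- seq_len(last_idx)
    dim_mm <- (6 * vol[keep] / pi)^(1 / 3)  # isotropic: L = W = D
    id <- sprintf("tumor%03d", i)
    lab <- label_one(vol[keep], days[keep])
    growth[[i]] <- data.frame(tumor_id = id, day = days[keep],
                              L = dim_mm, W = dim_mm, D = dim_mm,
                              volume = tumor_volume(dim_mm, dim_mm, dim_mm),
                              arm = arms[i], response_category = lab,
                              stringsAsFactors = FALSE)
    event <- as.integer(!censored_early && length(hit) > 0)
    surv[[i]] <- data.frame(subject_id = id, time = days[last_idx],
                            event = event, group = arms[i],
                            response_category = lab, stringsAsFactors = FALSE)
  }
  list(growth = do.call(rbind, growth), survival = do.call(rbind, surv))
}
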