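#' Simulate an LC-MS peak table coupled to a latent induction trajectory
#'
#' Target metabolite peaks carry m/z inside the configured diterpenoid mass
#' window, at least one fragment, and treated-condition intensities that rise
#' with the latent trajectory to `cfg$induction_fold` over control (times a
#' multiplicative log-normal noise); they are also most abundant in root bark.
#' Decoy peaks are unresponsive and split among three classes: in-window with
#' fragments, out-of-window with fragments, and fragmentless (in-window), so
#' each stage of the peak funnel has something to remove.
#'
#' @param cfg a [sim_config()].
#' @param latent latent trajectory over `cfg$time_points_h` (from
#'   [gen_expression()]); length must equal `length(cfg$time_points_h)`.
#' @param decoy_fractions numeric length-3 proportions (in-window,
#'   out-of-window, fragmentless) for the decoys; normalized internally.
#' @return list with `peaks` (a [peak_table()]) and `truth`
#'   (`target_metabolite_ids`).
#' @export
gen_metabolome <- function(cfg, latent,
                           decoy_fractions = c(0.4, 0.4, 0.2)) {
  validate_sim_config(cfg)
  if (length(latent) != length(cfg$time_points_h)) {
    stop("latent trajectory length must equal number of time points",
         call. = FALSE)
  }
  design <- make_design(cfg)
  n <- cfg$n_peaks
  nt <- cfg$n_target_metabolites
  if (nt >= n) stop("invalid config: all peaks would be targets", call. = FALSE)
  target_ids <- sprintf("M_TARGET%02d", seq_len(nt))
  decoy_ids <- sprintf("M_DECOY%03d", seq_len(n - nt))
  ids <- c(target_ids, decoy_ids)

  frac <- decoy_fractions / sum(decoy_fractions)
  n_dec <- n - nt
  n_out <- round(n_dec * frac[2])
  n_fragless <- round(n_dec * frac[3])
  n_in <- n_dec - n_out - n_fragless
  klass <- c(rep("target", nt), rep("in", n_in), rep("out", n_out),
             rep("fragless", n_fragless))

  with_stream(cfg, 12L, {
    lo <- cfg$mass_window[1]; hi <- cfg$mass_window[2]
    mz <- numeric(n)
    inwin <- klass %in% c("target", "in", "fragless")
    mz[inwin] <- stats::runif(sum(inwin), lo, hi)
    out_low <- stats::runif(n_out) < 0.5
    mz_out <- ifelse(out_low, stats::runif(n_out, 100, lo - 1e-3),
                     stats::runif(n_out, hi + 1e-3, 900))
    mz[klass == "out"] <- mz_out
    rt <- stats::runif(n, 0.5, 15)
    frag <- sample(1:8, n, replace = TRUE)
    frag[klass == "fragless"] <- 0L

    base <- exp(stats::rnorm(n, log(5e4), 0.7))
    mu <- matrix(rep(base, nrow(design)), nrow = n,
                 dimnames = list(ids, design$sample_id))
    tcol <- which(design$condition == "treated")
    ti <- seq_len(nt)
    for (j in tcol) {
      l <- latent[match(design$time_h[j], cfg$time_points_h)]
      mu[ti, j] <- base[ti] * (1 + (cfg$induction_fold - 1) * l)
    }
    tis <- which(design$condition == "tissue")
    rb <- which(design$tissue == "root_bark")
    mu[, tis] <- base * matrix(exp(stats::rnorm(n * length(tis), 0, 0.4)),
                               nrow = n)
    mu[ti, rb] <- base[ti] * 6
    mu[ti, setdiff(tis, rb)] <- base[ti] *
      matrix(stats::runif(nt * (length(tis) - 1L), 0.1, 0.5), nrow = nt)

    intens <- mu * exp(stats::rnorm(length(mu), 0, cfg$noise_sd))
    peaks <- data.frame(peak_id = ids, mz = mz, rt = rt,
                        fragment_count = as.integer(frag),
                        stringsAsFactors = FALSE)
    list(peaks = peak_table(peaks, intens, design),
         truth = list(target_metabolite_ids = target_ids))
  })
}
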