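# Parametric emulators of the per-gene (geometric mean, dispersion) pools that
# anchor the simulator.  The presets are synthetic stand-ins for pools harvested
# from real lymphoblastoid ("pickrell-like") and rat dorsal-root-ganglion
# ("hammer-like") RNA-seq data: they reproduce the qualitative contrasts between
# those datasets (the hammer-like pool has higher mean counts and lower, tighter
# dispersions; both pools show a decreasing dispersion-mean trend with
# heavy-tailed scatter), not any particular gene list.  All constants live here.
pool_presets <- list(
  `pickrell-like` = list(
    logmean_center = 1.6,   # natural-log geometric mean count, unimodal
    logmean_sd     = 1.8,
    disp_intercept = 0.3,   # log phi = a + b * log m + t-noise
    disp_slope     = -0.25,
    disp_noise_sd  = 0.8,   # scale of t_4 scatter around the trend
    disp_noise_df  = 4
  ),
  `hammer-like` = list(
    logmean_center = 4.5,
    logmean_sd     = 1.8,
    disp_intercept = -1.5,
    disp_slope     = -0.25,
    disp_noise_sd  = 0.25,
    disp_noise_df  = 4
  )
)

# Bounds applied to every pool, emulated or loaded: the dispersion floor mirrors
# the common minimum value genewise estimators assign to non-overdispersed
# genes, and the caps keep the NB sampler away from degenerate regimes.
.POOL_PHI_FLOOR <- 1e-4
.POOL_PHI_CAP <- 20
.POOL_MEAN_FLOOR <- 0.05

#' Emulate a (mean, dispersion) parameter pool
#'
#' Draws a pool of per-gene baseline geometric means and true dispersions from
#' a parametric model: log-means are normal with a preset center and spread,
#' and log-dispersions follow a decreasing linear trend in log-mean plus
#' heavy-tailed (Student-t) scatter. The \code{"pickrell-like"} preset has a
#' lower mean location and higher, wider dispersions than \code{"hammer-like"}.
#'
#' @param preset \code{"pickrell-like"} or \code{"hammer-like"}.
#' @param size Number of (mean, dispersion) pairs to draw.
#' @param seed Integer seed; the same preset/size/seed gives an identical pool.
#' @return A \code{param_pool}: data frame with columns \code{mean} and
#'   \code{dispersion} and a \code{source} attribute.
#' @examples
#' pool <- emulate_pool("hammer-like", 1000, seed = 1)
#' median(pool$dispersion)
#' @export
emulate_pool <- function(preset, size, seed) {
  if (!preset %in% names(pool_presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(pool_presets), collapse = ", "))
  p <- pool_presets[[preset]]
  set.seed(as.integer(seed))
  logm <- stats::rnorm(size, p$logmean_center, p$logmean_sd)
  m <- pmax(exp(logm), .POOL_MEAN_FLOOR)
  logphi <- p$disp_intercept + p$disp_slope * log(m) +
    p$disp_noise_sd * stats::rt(size, df = p$disp_noise_df)
  phi <- pmin(pmax(exp(logphi), .POOL_PHI_FLOOR), .POOL_PHI_CAP)
  new_param_pool(m, phi, source = preset)
}

new_param_pool <- function(means, dispersions, source) {
  stopifnot(length(means) == length(dispersions), all(means > 0),
            all(dispersions >= 0))
  structure(data.frame(mean = means, dispersion = dispersions),
            source = source, class = c("param_pool", "data.frame"))
}

#' Load a (mean, dispersion) pool from TSV
#'
#' Reads a tab-separated file with header columns \code{mean} and
#' \code{dispersion}. Rows with non-positive means are dropped with a message
#' reporting how many were rejected; dispersions are floored at a small
#' positive minimum.
#'
#' @param path File path.
#' @return A \code{param_pool}.
#' @export
load_pool <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse pool file '", path,
                                          "': ", conditionMessage(e)))
  if (!all(c("mean", "dispersion") %in% colnames(df)))
    stop("pool file must have 'mean' and 'dispersion' columns")
  if (!is.numeric(df$mean) || !is.numeric(df$dispersion)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$mean))) |
                 is.na(suppressWarnings(as.numeric(df$dispersion))))
    stop("non-numeric pool entries at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  keep <- df$mean > 0
  if (any(!keep))
    message(sum(!keep), " pool row(s) with non-positive mean rejected")
  df <- df[keep, , drop = FALSE]
  new_param_pool(df$mean, pmax(df$dispersion, .POOL_PHI_FLOOR),
                 source = paste0("file:", path))
}

#' Write a pool to TSV
#'
#' @param pool A \code{param_pool}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pool <- function(pool, path) {
  utils::write.table(data.frame(mean = pool$mean, dispersion = pool$dispersion),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
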