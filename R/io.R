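# Trajectory CSV format: '#'-prefixed metadata header carrying the full
# parameter set, then columns time_h, signal_nM, P at 12 significant
# digits.  Written with fixed formatting so that write -> read -> write is
# bit-identical.

#' Write a trajectory to CSV
#'
#' @param trajectory A `ph_trajectory` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ph_trajectory"))
  p <- attr(trajectory, "params")
  s <- attr(trajectory, "forcing")
  hdr <- c(
    sprintf("# pulsehill trajectory (method: %s)", attr(trajectory, "method")),
    sprintf("# n: %.12g", p$n),
    sprintf("# k1_per_nMn_h: %.12g", p$k1),
    sprintf("# k2_per_h: %.12g", p$k2),
    sprintf("# K_A_nM: %.12g", p$K_A),
    sprintf("# amplitude_nM: %.12g", s$amplitude),
    sprintf("# period_h: %.12g", s$period),
    sprintf("# duty_cycle: %.12g", s$duty_cycle)
  )
  body <- sprintf("%.12g,%.12g,%.12g",
                  trajectory$time, trajectory$signal, trajectory$P)
  writeLines(c(hdr, "time_h,signal_nM,P", body), path)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the data columns and reconstructs the parameter attributes from
#' the metadata header.
#'
#' @param path File path.
#' @return A `ph_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in grep("^# [A-Za-z0-9_]+: ", hdr, value = TRUE)) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- as.numeric(sub("^[^:]+: ", "", kv))
  }
  method <- sub("^# pulsehill trajectory \\(method: (.*)\\)$", "\\1",
                hdr[1])
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  params <- hill_params(n = meta$n, k1 = meta$k1_per_nMn_h,
                        k2 = meta$k2_per_h)
  forcing <- square_wave(meta$amplitude_nM, meta$period_h, meta$duty_cycle)
  new_trajectory(dat$time_h, dat$signal_nM, dat$P, params, forcing, method)
}
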