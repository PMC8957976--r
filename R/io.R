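#' Write and read subject recordings as TSV plus JSON sidecar
#'
#' The BOLD matrix is written as a tab-separated table (scans x regions,
#' header = region labels) and the metadata (TR, group, seed, noise SD and,
#' for synthetic subjects, the ground-truth parameters) as a JSON sidecar
#' next to it (`<path>.json`).
#'
#' @param recording A `subject_recording`.
#' @param path Path of the TSV file.
#' @return `write_recording` returns the path invisibly; `read_recording`
#'   returns a `subject_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "subject_recording"))
  utils::write.table(recording$bold, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(tr = recording$tr, regions = recording$regions,
               group = recording$group, seed = recording$seed,
               noise_sd = recording$noise_sd)
  if (!is.null(recording$truth)) {
    tp <- recording$truth
    meta$truth <- list(variant = tp$variant, a = tp$a, c = tp$c, d = tp$d,
                       hemo = tp$hemo, noise_sd = tp$noise_sd, snr = tp$snr)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  bold <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  regions <- as.character(meta$regions)
  colnames(bold) <- regions
  truth <- NULL
  if (!is.null(meta$truth)) {
    spec <- cmc_spec(meta$truth$variant, n_regressors = ncol(meta$truth$c))
    truth <- dcm_parameters(
      matrix(meta$truth$a, length(regions)),
      matrix(meta$truth$c, length(regions)),
      as.numeric(meta$truth$d), spec,
      hemo = as.data.frame(meta$truth$hemo),
      noise_sd = if (is.null(meta$truth$noise_sd)) NA_real_
                 else meta$truth$noise_sd,
      snr = meta$truth$snr
    )
  }
  structure(
    list(bold = bold, tr = meta$tr, regions = regions,
         group = if (is.null(meta$group)) NA_character_ else meta$group,
         seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
         truth = truth,
         noise_sd = if (is.null(meta$noise_sd)) NA_real_ else meta$noise_sd),
    class = "subject_recording"
  )
}

#' Write a synthetic cohort to a directory
#'
#' Writes one TSV + sidecar per subject and a `manifest.tsv` listing
#' subject ids, groups and seeds.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$recordings)) {
    write_recording(cohort$recordings[[i]],
                    file.path(dir, paste0(cohort$manifest$subject[i],
                                          ".tsv")))
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
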