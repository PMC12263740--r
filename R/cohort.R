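#' Cohort containers
#'
#' A cohort is a plain `data.frame` (class `nlmr_cohort`) with one row per
#' simulated individual and columns for every stored component of the
#' generating model: `id`, the instrument `g`, the latent variables `u` (and
#' `v` where the model has one), the error terms `e_x`, `e_y`, the exposure
#' `x` and outcome `y`, a per-individual genetic effect `alpha` where the
#' model draws one, and any named modifier columns. The generating
#' configuration is attached as the `"config"` attribute so that `x` and `y`
#' are recomputable bit-exactly from the stored components.
#'
#' @name nlmr_cohort
NULL

new_cohort <- function(df, config = NULL, modifiers = character()) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  structure(df,
            config = config,
            modifiers = modifiers,
            class = c("nlmr_cohort", "data.frame"))
}

#' @export
print.nlmr_cohort <- function(x, ...) {
  cat(sprintf("<nlmr_cohort> n = %d, columns: %s\n",
              nrow(x), paste(names(x), collapse = ", ")))
  cfg <- attr(x, "config")
  if (!is.null(cfg$model_id)) cat("  generating model:", cfg$model_id, "\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Write / read a cohort as tab-separated text
#'
#' Round-trips the per-individual columns (`id`, `g`, `u`, `v`, `e_x`,
#' `e_y`, `x`, `y`, `alpha`, modifier columns); optional columns absent from
#' the cohort are simply omitted from the file and tolerated on read. The
#' generating configuration is not serialized here (see [config_to_yaml()]).
#'
#' @param cohort an `nlmr_cohort` (or any data.frame with an `id` column).
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `nlmr_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!"id" %in% names(df)) stop("cohort file lacks an 'id' column",
                                 call. = FALSE)
  known <- c("id", "g", "u", "v", "e_x", "e_y", "x", "y", "alpha")
  new_cohort(df, modifiers = setdiff(names(df), known))
}
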