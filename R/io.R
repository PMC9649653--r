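# CSV readers/writers for the pipeline's interchange formats. All files are
# UTF-8 CSV with '#'-prefixed provenance header lines.

#' Write a result table as CSV with provenance headers
#'
#' Prepends '#'-prefixed comment lines recording the producing command,
#' package version and seed, so every output is re-runnable from its
#' header. Readers in this package skip comment lines.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param command Free-text description of the producing command/call.
#' @param seed Seed used (or `NA`).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, command = "", seed = NA) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# egfr19 %s",
                     as.character(utils::packageVersion("egfr19"))), con)
  if (nzchar(command)) writeLines(paste("# command:", command), con)
  writeLines(paste("# seed:", seed), con)
  writeLines(paste("# written:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance headers
#'
#' @param path CSV path; lines starting with '#' are ignored.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (nrow(df) == 0L) stop("input file has no data rows: ", path)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(sprintf("input %s is missing required column(s): %s",
                   path, paste(missing, collapse = ", ")))
    }
  }
  df
}

#' Read a DynamX-style HDX peptide cluster table
#'
#' Expects columns `sequence`, `start`, `end`, `charge`, `state`,
#' `exposure_s`, `replicate` and `centroid_mass_da` (or `centroid_mz`,
#' converted via the charge assuming protonation). Reference rows are
#' `exposure_s == 0` (undeuterated, m_0) and `state == "FD"`
#' (fully-deuterated, m_f); per peptide/charge both must be present.
#'
#' @param path CSV path.
#' @return List of `exchange_record` objects, one per peptide/charge.
#' @export
read_hdx_cluster_csv <- function(path) {
  df <- read_pipeline_csv(path, required = c("sequence", "start", "end",
                                             "charge", "state", "exposure_s",
                                             "replicate"))
  if (!"centroid_mass_da" %in% names(df)) {
    if (!"centroid_mz" %in% names(df)) {
      stop("need a centroid_mass_da or centroid_mz column")
    }
    df$centroid_mass_da <- df$centroid_mz * df$charge -
      (df$charge - 1) * 1.00728
  }
  keys <- unique(df[, c("sequence", "start", "end", "charge")])
  records <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$sequence == k$sequence & df$charge == k$charge &
                df$start == k$start & df$end == k$end, ]
    m0 <- mean(sub$centroid_mass_da[sub$exposure_s == 0 & sub$state != "FD"])
    mf <- mean(sub$centroid_mass_da[sub$state == "FD"])
    if (!is.finite(m0) || !is.finite(mf)) {
      stop(sprintf("peptide %s/%d+ lacks undeuterated and/or fully-deuterated reference rows",
                   k$sequence, k$charge))
    }
    lab <- sub[sub$exposure_s > 0 & sub$state != "FD", ]
    tps <- sort(unique(lab$exposure_s))
    reps <- sort(unique(lab$replicate))
    m_t <- matrix(NA_real_, nrow = length(reps), ncol = length(tps))
    for (r in seq_along(reps)) for (tt in seq_along(tps)) {
      v <- lab$centroid_mass_da[lab$replicate == reps[r] &
                                  lab$exposure_s == tps[tt]]
      if (length(v)) m_t[r, tt] <- mean(v)
    }
    percent_exchange(tps, m_t, m0, mf,
                     start_res = k$start, end_res = k$end,
                     peptide_id = sprintf("%s_%d_%d_z%d", k$sequence,
                                          k$start, k$end, k$charge))
  })
  records
}

#' Flatten exchange records to a tidy per-peptide table
#'
#' @param records List of `exchange_record` objects.
#' @return Data frame with columns `peptide_id`, `start_res`, `end_res`,
#'   `median_residue`, `timepoint`, `percent`, `sd`.
#' @export
exchange_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(peptide_id = as.character(r$peptide_id),
               start_res = r$start_res, end_res = r$end_res,
               median_residue = r$median_residue,
               timepoint = r$timepoints,
               percent = r$percent, sd = r$sd,
               stringsAsFactors = FALSE)
  }))
}
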