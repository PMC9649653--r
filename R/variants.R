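# Parsing and classification of EGFR exon 19 variant descriptors.

#' Parse an exon 19 variant descriptor
#'
#' Accepts the delta notation used in the clinical kinase literature
#' ("ΔE746-A750", "ΔL747-A750InsP"), HGVS-like protein notation
#' ("E746_A750del", "L747_A750delinsP", "E746_S752delinsV") and single-residue
#' substitutions ("L747P"). Keyword case is ignored ("Ins"/"ins"/"INS"), the
#' Unicode Greek delta and the ASCII "del"/"Del" prefix are interchangeable,
#' whitespace is stripped and en-dashes are treated as hyphens.
#'
#' Every stated reference residue (substitution reference, range endpoints)
#' is validated against `context`; a mismatch is an error. Variants whose
#' deletion extends beyond the configured loop window raise a warning but are
#' still parsed as long as at least one deleted residue lies in the window.
#'
#' @param descriptor Variant descriptor string.
#' @param context An [egfr_reference()] object.
#' @return An object of class `exon19_variant`: a list with fields
#'   `raw_descriptor`, `deletion_start`, `deletion_end`, `deleted_count`,
#'   `inserted_sequence`, `substitution` (list with `position`, `ref_aa`,
#'   `alt_aa`, or `NULL`), and `net_loop_shortening`
#'   (= deleted - inserted residues).
#' @examples
#' ctx <- egfr_reference()
#' parse_variant("ΔE746-A750", ctx)$deleted_count        # 5
#' parse_variant("E746_S752delinsV", ctx)$net_loop_shortening # 6
#' @export
parse_variant <- function(descriptor, context = egfr_reference()) {
  stopifnot(inherits(context, "egfr_reference"))
  if (length(descriptor) != 1L || is.na(descriptor) || !nzchar(trimws(descriptor))) {
    stop("descriptor must be a single non-empty string")
  }
  raw <- descriptor
  d <- gsub("\\s", "", descriptor)
  # normalise dash variants (en/em dash, minus sign) to ASCII hyphen
  d <- gsub("[‐‑‒–—−]", "-", d)
  du <- toupper(d)

  variant <- NULL

  # HGVS-like: E746_A750del, L747_A750delinsP, E746del
  m <- regmatches(du, regexec(
    "^([A-Z])([0-9]+)(?:_([A-Z])([0-9]+))?DEL(?:INS([A-Z]+))?$", du))[[1]]
  if (length(m)) {
    start_aa <- m[2]; start <- as.integer(m[3])
    end_aa <- if (nzchar(m[4])) m[4] else m[2]
    end <- if (nzchar(m[5])) as.integer(m[5]) else start
    ins <- m[6]
    variant <- .build_deletion(raw, context, start_aa, start, end_aa, end, ins)
  }

  # Delta notation: ΔE746-A750, delE746-A750, ΔL747-A750InsP, ΔE746
  if (is.null(variant)) {
    m <- regmatches(du, regexec(
      "^(Δ|DEL)([A-Z])([0-9]+)(?:-([A-Z])([0-9]+))?(?:INS([A-Z]+))?$", du))[[1]]
    if (length(m)) {
      start_aa <- m[3]; start <- as.integer(m[4])
      end_aa <- if (nzchar(m[5])) m[5] else m[3]
      end <- if (nzchar(m[6])) as.integer(m[6]) else start
      ins <- m[7]
      variant <- .build_deletion(raw, context, start_aa, start, end_aa, end, ins)
    }
  }

  # Point substitution: L747P
  if (is.null(variant)) {
    m <- regmatches(du, regexec("^([A-Z])([0-9]+)([A-Z])$", du))[[1]]
    if (length(m)) {
      pos <- as.integer(m[3])
      .check_range(context, pos, pos)
      .check_ref(context, pos, m[2], raw)
      variant <- .new_variant(raw,
                              deletion_start = NA_integer_,
                              deletion_end = NA_integer_,
                              deleted_count = 0L,
                              inserted_sequence = "",
                              substitution = list(position = pos,
                                                  ref_aa = m[2],
                                                  alt_aa = m[4]))
    }
  }

  if (is.null(variant)) {
    stop(sprintf("cannot parse variant descriptor %s: unrecognised token %s",
                 sQuote(raw), sQuote(d)))
  }
  variant
}

.new_variant <- function(raw, deletion_start, deletion_end, deleted_count,
                         inserted_sequence, substitution) {
  structure(
    list(raw_descriptor = raw,
         deletion_start = deletion_start,
         deletion_end = deletion_end,
         deleted_count = deleted_count,
         inserted_sequence = inserted_sequence,
         substitution = substitution,
         net_loop_shortening = deleted_count - nchar(inserted_sequence)),
    class = "exon19_variant"
  )
}

.check_range <- function(context, start, end) {
  if (start < context$seq_start || end > context$seq_end) {
    stop(sprintf("residue range %d-%d falls outside the reference interval %d-%d",
                 start, end, context$seq_start, context$seq_end))
  }
}

.check_ref <- function(context, position, stated, raw) {
  actual <- ref_residue(context, position)
  if (!identical(actual, stated)) {
    stop(sprintf(
      "reference mismatch in %s: position %d is %s in the reference, descriptor states %s",
      sQuote(raw), position, actual, stated))
  }
  invisible(TRUE)
}

.build_deletion <- function(raw, context, start_aa, start, end_aa, end, ins) {
  if (end < start) {
    stop(sprintf("deletion end %d precedes start %d in %s", end, start, sQuote(raw)))
  }
  .check_range(context, start, end)
  .check_ref(context, start, start_aa, raw)
  .check_ref(context, end, end_aa, raw)
  in_window <- sum(seq(start, end) >= context$loop_start &
                     seq(start, end) <= context$loop_end)
  if (in_window == 0L) {
    stop(sprintf("deletion %d-%d lies entirely outside the loop window %d-%d",
                 start, end, context$loop_start, context$loop_end))
  }
  if (start < context$loop_start || end > context$loop_end) {
    warning(sprintf(
      "deletion %d-%d in %s extends beyond the configured loop window %d-%d; classifying on the full deletion",
      start, end, raw, context$loop_start, context$loop_end))
  }
  .new_variant(raw,
               deletion_start = start,
               deletion_end = end,
               deleted_count = end - start + 1L,
               inserted_sequence = ins,
               substitution = NULL)
}

#' Canonical delta-notation serialisation of a parsed variant
#'
#' @param variant An `exon19_variant`.
#' @param context Reference context used to recover residue identities.
#' @return Canonical descriptor string, e.g. `"ΔL747-A750InsP"` or
#'   `"L747P"`; `parse_variant(format_variant(v))` reproduces `v`.
#' @export
format_variant <- function(variant, context = egfr_reference()) {
  stopifnot(inherits(variant, "exon19_variant"))
  if (!is.null(variant$substitution)) {
    s <- variant$substitution
    return(sprintf("%s%d%s", s$ref_aa, s$position, s$alt_aa))
  }
  if (variant$deleted_count == 0L) return("WT")
  out <- sprintf("Δ%s%d", ref_residue(context, variant$deletion_start),
                 variant$deletion_start)
  if (variant$deletion_end > variant$deletion_start) {
    out <- sprintf("%s-%s%d", out, ref_residue(context, variant$deletion_end),
                   variant$deletion_end)
  }
  if (nzchar(variant$inserted_sequence)) {
    out <- sprintf("%sIns%s", out, variant$inserted_sequence)
  }
  out
}

#' @export
print.exon19_variant <- function(x, ...) {
  cat("EGFR exon 19 variant:", x$raw_descriptor, "\n")
  if (!is.null(x$substitution)) {
    s <- x$substitution
    cat(sprintf("  substitution: %s%d%s\n", s$ref_aa, s$position, s$alt_aa))
  }
  if (x$deleted_count > 0L) {
    cat(sprintf("  deletion: %d-%d (%d residues)", x$deletion_start,
                x$deletion_end, x$deleted_count))
    if (nzchar(x$inserted_sequence)) cat(", inserted:", x$inserted_sequence)
    cat("\n")
  }
  cat("  net beta3/alphaC loop shortening:", x$net_loop_shortening, "\n")
  invisible(x)
}

#' Apply a variant to the reference sequence
#'
#' Splices the parsed deletion/insertion (or substitution) into the reference
#' interval and returns the mutant sequence. Output length equals the
#' reference length minus the net loop shortening.
#'
#' @inheritParams format_variant
#' @return Mutant one-letter amino-acid string for the reference interval.
#' @examples
#' ctx <- egfr_reference()
#' v <- parse_variant("ΔL747-E749", ctx)
#' apply_variant(v, ctx) # reference with "LRE" removed
#' @export
apply_variant <- function(variant, context = egfr_reference()) {
  stopifnot(inherits(variant, "exon19_variant"),
            inherits(context, "egfr_reference"))
  chars <- strsplit(context$sequence, "")[[1]]
  if (!is.null(variant$substitution)) {
    s <- variant$substitution
    chars[s$position - context$seq_start + 1L] <- s$alt_aa
    return(paste(chars, collapse = ""))
  }
  if (variant$deleted_count == 0L) return(context$sequence)
  i0 <- variant$deletion_start - context$seq_start + 1L
  i1 <- variant$deletion_end - context$seq_start + 1L
  left <- if (i0 > 1L) chars[seq_len(i0 - 1L)] else character(0)
  right <- if (i1 < length(chars)) chars[seq(i1 + 1L, length(chars))] else character(0)
  paste(c(left, strsplit(variant$inserted_sequence, "")[[1]], right),
        collapse = "")
}

#' Classify a variant as sensitivity profile 1 or profile 2
#'
#' Profile membership is determined by the net shortening of the beta3/alphaC
#' loop: variants with a net deletion of three or fewer residues are
#' profile 1 (wild-type-like ATP affinity, primary resistance to erlotinib
#' and osimertinib expected), while a net deletion of four or more residues
#' places a variant in profile 2 (raised Michaelis constant for ATP,
#' sensitivity to first- and third-generation inhibitors retained).
#' Insertions count at face value: net shortening = residues deleted minus
#' residues inserted, regardless of insertion composition. Substitutions
#' count as net zero. A proline introduced within the loop (by insertion or
#' substitution) is flagged, since short deletions can still activate the
#' kinase when they introduce a proline; `activation_predicted` is true for
#' any profile 2 variant or any proline-introducing variant.
#'
#' @param variant An `exon19_variant` from [parse_variant()].
#' @return An object of class `profile_call`: list with `profile` (1 or 2),
#'   `net_loop_shortening`, `proline_introduced`, `activation_predicted`,
#'   `rationale`.
#' @examples
#' ctx <- egfr_reference()
#' classify_profile(parse_variant("ΔE746-A750", ctx))$profile      # 2
#' classify_profile(parse_variant("ΔL747-A750InsP", ctx))$profile  # 1
#' @export
classify_profile <- function(variant) {
  stopifnot(inherits(variant, "exon19_variant"))
  net <- variant$net_loop_shortening
  if (net < 0L) {
    stop(sprintf(
      "variant %s is a net insertion (net shortening %d); the profile rule applies only to loop-shortening exon 19 variants",
      sQuote(variant$raw_descriptor), net))
  }
  proline <- grepl("P", variant$inserted_sequence, fixed = TRUE) ||
    (!is.null(variant$substitution) && variant$substitution$alt_aa == "P")
  profile <- if (net <= 3L) 1L else 2L
  rationale <- sprintf(
    "net loop shortening %d (%s 3) => profile %d%s",
    net, if (net <= 3L) "≤" else ">", profile,
    if (proline) "; proline introduced in loop" else "")
  structure(
    list(profile = profile,
         net_loop_shortening = net,
         proline_introduced = proline,
         activation_predicted = profile == 2L || proline,
         rationale = rationale),
    class = "profile_call"
  )
}

#' @export
print.profile_call <- function(x, ...) {
  cat(sprintf("Profile %d call (%s)\n", x$profile, x$rationale))
  invisible(x)
}

#' Classify a vector of variant descriptors
#'
#' Vectorised convenience wrapper around [parse_variant()] and
#' [classify_profile()] producing one row per descriptor.
#'
#' @param descriptors Character vector of variant descriptors.
#' @param context An [egfr_reference()] object.
#' @return Data frame with columns `descriptor`, `deletion_start`,
#'   `deletion_end`, `deleted_count`, `inserted`, `net_shortening`,
#'   `proline`, `profile`, `activation_predicted`.
#' @export
classify_variants <- function(descriptors, context = egfr_reference()) {
  rows <- lapply(descriptors, function(d) {
    v <- parse_variant(d, context)
    p <- classify_profile(v)
    data.frame(descriptor = d,
               deletion_start = if (is.na(v$deletion_start)) NA_integer_ else v$deletion_start,
               deletion_end = if (is.na(v$deletion_end)) NA_integer_ else v$deletion_end,
               deleted_count = v$deleted_count,
               inserted = v$inserted_sequence,
               net_shortening = v$net_loop_shortening,
               proline = p$proline_introduced,
               profile = p$profile,
               activation_predicted = p$activation_predicted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
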