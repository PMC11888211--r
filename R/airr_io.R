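#' Read a germline V reference multiple sequence alignment
#'
#' Reads a FASTA file of aligned germline V alleles ('-' gaps) and builds the
#' coordinate system the chimera HMM emits over: every row must have the same
#' length, and each reference gets a map from ungapped germline position to
#' alignment column. Sequences are uppercased and U is normalized to T.
#'
#' @param path path to a FASTA file.
#' @return a `reference_msa` object; see [as_reference_msa()].
#' @export
read_reference_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  as_reference_msa(setNames(as.character(ss), nm))
}

#' Construct a reference MSA from named sequences
#'
#' @param seqs named character vector of equal-length gapped sequences over
#'   \{A,C,G,T,N,-\} (case-insensitive; U is mapped to T).
#' @return a `reference_msa`: list with `names`, `seqs`, `mat` (N x L character
#'   matrix), `codes` (N x L integer matrix, A/C/G/T = 0..3, gap/N = 4), `L`,
#'   `N`, and `col_map` (per reference, ungapped position -> alignment column).
#' @export
as_reference_msa <- function(seqs) {
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all reference sequences must have nonempty names")
  if (anyDuplicated(nm))
    stop("duplicate reference name: ", nm[duplicated(nm)][1L])
  seqs <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1L])[1L]
    stop("not an alignment: record '", nm[off], "' has length ", lens[off],
         " but '", nm[1L], "' has length ", lens[1L])
  }
  L <- lens[[1L]]
  if (L < 1L) stop("alignment has zero columns")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ok <- matrix(mat %in% c("A", "C", "G", "T", "N", "-"), nrow = length(nm))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("invalid symbol '", mat[bad[1L], bad[2L]], "' in record '",
         nm[bad[1L]], "' at column ", bad[2L])
  }
  codes <- matrix(encode_symbols(mat), nrow = length(nm))
  col_map <- lapply(seq_along(nm), function(i) which(mat[i, ] != "-"))
  names(col_map) <- nm
  structure(
    list(names = nm, seqs = unname(seqs), mat = mat, codes = codes,
         L = L, N = length(nm), col_map = col_map),
    class = "reference_msa")
}

#' @export
print.reference_msa <- function(x, ...) {
  cat("reference_msa: ", x$N, " sequences x ", x$L, " columns\n", sep = "")
  cat("  ", paste(head(x$names, 5L), collapse = ", "),
      if (x$N > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

AIRR_REQUIRED <- c("sequence_id", "v_call", "v_sequence_alignment",
                   "v_germline_alignment", "v_germline_start", "v_germline_end")

#' Read an AIRR Rearrangement TSV
#'
#' All columns are kept as character so that unknown columns round-trip
#' byte-for-byte through [write_detect_output()]. Rows with an empty
#' `v_sequence_alignment` are unusable for threading and are dropped with a
#' message; the count is attached as attribute `skipped_empty`.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a `data.table`, one row per usable rearrangement.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, showProgress = FALSE)
  missing <- setdiff(AIRR_REQUIRED, names(dt))
  if (length(missing))
    stop("missing required AIRR columns: ", paste(missing, collapse = ", "))
  empty <- !nzchar(dt$v_sequence_alignment)
  if (any(empty)) {
    message(sum(empty), " record(s) with empty v_sequence_alignment skipped")
    dt <- dt[!empty]
  }
  if (nrow(dt) == 0L) warning("no usable records in ", path)
  data.table::setattr(dt, "skipped_empty", sum(empty))
  dt[]
}

#' Thread one AIRR query onto the reference MSA
#'
#' Projects the query into MSA column space using its existing V alignment, so
#' the HMM never re-aligns: walking the paired alignment strings with a
#' germline-position counter starting at `v_germline_start`, each query symbol
#' opposite a germline base lands at that base's alignment column. Query
#' insertions (germline '-') are dropped; uncovered columns stay '-'
#' (emission-neutral), which is how partial-V reads are handled. Symbols
#' outside \{A,C,G,T,-\} become N.
#'
#' @param q a list or one-row data.frame with the required AIRR fields.
#' @param msa a `reference_msa`.
#' @return list with `sequence_id`, `obs` (character vector of length
#'   `msa$L` over \{A,C,G,T,-,N\}) and `assigned_v` (first allele of `v_call`).
#' @export
thread_query <- function(q, msa) {
  v <- trimws(strsplit(q$v_call[[1L]], ",", fixed = TRUE)[[1L]][1L])
  if (!v %in% msa$names) {
    stop(structure(
      class = c("vchimera_unknown_reference", "error", "condition"),
      list(message = paste0("unknown reference '", v, "' for query '",
                            q$sequence_id[[1L]], "'"),
           call = sys.call(-1L))))
  }
  g <- strsplit(toupper(q$v_germline_alignment[[1L]]), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(q$v_sequence_alignment[[1L]]), "", fixed = TRUE)[[1L]]
  if (length(g) != length(s))
    stop("malformed record '", q$sequence_id[[1L]],
         "': sequence and germline alignments differ in length")
  keep <- g != "-"
  gs <- as.integer(q$v_germline_start[[1L]])
  ge <- as.integer(q$v_germline_end[[1L]])
  if (is.na(gs) || gs < 1L || is.na(ge) || ge < gs)
    stop("malformed record '", q$sequence_id[[1L]],
         "': invalid v_germline_start/v_germline_end")
  if (sum(keep) != ge - gs + 1L)
    stop("malformed record '", q$sequence_id[[1L]],
         "': germline alignment length disagrees with v_germline_start/end")
  cm <- msa$col_map[[v]]
  pos <- gs + cumsum(keep) - 1L
  pos <- pos[keep]
  if (length(pos) && max(pos) > length(cm))
    stop("malformed record '", q$sequence_id[[1L]],
         "': germline position ", max(pos), " exceeds ungapped length ",
         length(cm), " of reference '", v, "'")
  obs <- rep("-", msa$L)
  qc <- s[keep]
  qc <- gsub("U", "T", qc, fixed = TRUE)
  qc[!qc %in% c("A", "C", "G", "T", "-")] <- "N"
  obs[cm[pos]] <- qc
  list(sequence_id = q$sequence_id[[1L]], obs = obs, assigned_v = v)
}

#' Thread a table of AIRR queries onto the reference MSA
#'
#' @param airr data.frame/data.table as returned by [read_airr()].
#' @param msa a `reference_msa`.
#' @param strict if `TRUE`, an allele absent from the MSA is a fatal error;
#'   otherwise such queries are skipped and counted.
#' @return list with `obs_codes` (integer matrix `msa$L` x n_kept; A/C/G/T =
#'   0..3, '-' /N = 4), `sequence_id`, `assigned_v`, `kept` (row indices into
#'   `airr`), and `n_skipped_unknown`.
#' @export
thread_queries <- function(airr, msa, strict = FALSE) {
  n <- nrow(airr)
  obs_codes <- matrix(4L, nrow = msa$L, ncol = n)
  kept <- logical(n)
  ids <- character(n)
  vs <- character(n)
  n_unknown <- 0L
  for (i in seq_len(n)) {
    tq <- tryCatch(thread_query(airr[i, ], msa),
                   vchimera_unknown_reference = function(e) e)
    if (inherits(tq, "vchimera_unknown_reference")) {
      if (strict) stop(tq)
      n_unknown <- n_unknown + 1L
      next
    }
    kept[i] <- TRUE
    ids[i] <- tq$sequence_id
    vs[i] <- tq$assigned_v
    obs_codes[, i] <- encode_symbols(tq$obs)
  }
  if (n_unknown > 0L)
    message(n_unknown, " query(ies) with v_call absent from the MSA skipped")
  list(obs_codes = obs_codes[, kept, drop = FALSE],
       sequence_id = ids[kept], assigned_v = vs[kept],
       kept = which(kept), n_skipped_unknown = n_unknown)
}

#' Write detection output as AIRR TSV
#'
#' All input columns are preserved in order; the appended columns are
#' `chimera_probability` (decimal, >= 6 significant digits), `chimera`
#' ("T"/"F"), and, when Viterbi segmentations are supplied,
#' `chimera_segments` ("allele:start-end" joined with ';', MSA columns) and
#' `chimera_breakpoints` (';'-joined columns).
#'
#' @param records data.frame/data.table of retained input rows.
#' @param calls data.frame with numeric `posterior`, logical `chimera`, and
#'   optional character `segments` and `breakpoints`.
#' @param path output path.
#' @return summary list (rows written, chimeric count), invisibly.
#' @export
write_detect_output <- function(records, calls, path) {
  if (nrow(records) != nrow(calls))
    stop("records (", nrow(records), ") and calls (", nrow(calls),
         ") differ in length")
  out <- data.table::as.data.table(records)
  out <- data.table::copy(out)
  out[, chimera_probability := vapply(
    calls$posterior, function(p) format(p, digits = 7, scientific = FALSE,
                                        trim = TRUE), character(1L))]
  out[, chimera := ifelse(calls$chimera, "T", "F")]
  if (!is.null(calls$segments)) {
    out[, chimera_segments := calls$segments]
    out[, chimera_breakpoints := calls$breakpoints]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(list(written = nrow(out), chimeric = sum(calls$chimera)))
}
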