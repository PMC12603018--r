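# Reading, validating, filtering and writing clone tables in the AIRR
# Rearrangement and MiXCR-like TSV dialects, and aggregation of rows into
# clonotypes keyed by the CDR3 amino-acid sequence.

.airr_mandatory <- c("junction_aa", "v_call", "d_call", "j_call",
                     "duplicate_count", "productive")
.mixcr_mandatory <- c("aaSeqCDR3", "nSeqCDR3", "cloneCount",
                      "allVHitsWithScore", "allDHitsWithScore",
                      "allJHitsWithScore")

#' Normalize an IGHV allele call to its subgroup label
#'
#' Collapses a full V-gene call such as `"IGHV11-2*01"` to the subgroup
#' (`"IGHV11"`) at which repertoire statistics are stratified. The subgroup
#' is the prefix of the call up to (excluding) the first `-`, `*` or `S`.
#'
#' @param v_call Character vector of V calls; every element must start with
#'   `"IGHV"`.
#' @return Character vector of subgroup labels.
#' @examples
#' normalize_ighv(c("IGHV11-2*01", "IGHV1-55"))
#' @export
normalize_ighv <- function(v_call) {
  if (length(v_call) == 0L) return(character(0))
  bad <- is.na(v_call) | !startsWith(v_call, "IGHV")
  if (any(bad)) {
    stop("not an IGHV call: ", paste(unique(v_call[bad]), collapse = ", "),
         call. = FALSE)
  }
  m <- regexpr("^IGHV[^-*S]*", v_call)
  regmatches(v_call, m)
}

# first hit of a MiXCR "allXHitsWithScore" field, score stripped:
# "IGHV11-2*01(1200),IGHV11-1*01(900)" -> "IGHV11-2*01"
.mixcr_first_hit <- function(x) {
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*\\)$", "", x)
  x[!nzchar(x)] <- NA_character_
  x
}

.parse_count <- function(x, path, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s '%s' at data row %d",
                 path, col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

.opt_col <- function(tab, name, default = NA) {
  if (name %in% names(tab)) tab[[name]] else rep(default, nrow(tab))
}

#' Read a clone table
#'
#' Reads one sample's clone table in either the AIRR Rearrangement TSV
#' dialect (columns `junction_aa`, `v_call`, `d_call`, `j_call`,
#' `duplicate_count`, `productive`, optional `junction`, `n1_length`,
#' `n2_length`, `consensus_quality`) or a MiXCR-like clone TSV
#' (`aaSeqCDR3`, `nSeqCDR3`, `cloneCount`, `allVHitsWithScore`, ...,
#' optional `nLengthVDJunction`, `nLengthDJJunction`, `avrgQualCDR3`).
#' Gene calls are normalized to IGHV subgroup form in `v_gene`; the full
#' allele is retained in `v_call`. Unknown optional columns are ignored.
#'
#' @param path Path to a TSV file.
#' @param dialect `"airr"` or `"mixcr"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension unless the table carries a `sample_id` column.
#' @return A tibble of clone records (one row per input row) with columns
#'   `sample_id`, `v_call`, `v_gene`, `d_gene`, `j_gene`, `cdr3_aa`,
#'   `cdr3_nt`, `read_count`, `n1_len`, `n2_len`, `productive`,
#'   `mean_quality`.
#' @export
read_clone_table <- function(path, dialect = c("airr", "mixcr"),
                             sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- if (dialect == "airr") .airr_mandatory else .mixcr_mandatory
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory %s column(s): %s", path, dialect,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(tab) && nrow(tab) > 0)
      tab$sample_id[1] else sub("\\.[^.]*$", "", basename(path))
  }
  if (nrow(tab) == 0L) {
    return(tibble::tibble(
      sample_id = character(0), v_call = character(0), v_gene = character(0),
      d_gene = character(0), j_gene = character(0), cdr3_aa = character(0),
      cdr3_nt = character(0), read_count = numeric(0), n1_len = numeric(0),
      n2_len = numeric(0), productive = logical(0), mean_quality = numeric(0)
    ))
  }
  if (dialect == "airr") {
    v_call <- tab$v_call
    rec <- tibble::tibble(
      sample_id = sample_id,
      v_call = v_call,
      v_gene = normalize_ighv(v_call),
      d_gene = .opt_col(tab, "d_call", NA_character_),
      j_gene = tab$j_call,
      cdr3_aa = tab$junction_aa,
      cdr3_nt = .opt_col(tab, "junction", NA_character_),
      read_count = .parse_count(tab$duplicate_count, path, "duplicate_count"),
      n1_len = .parse_count(.opt_col(tab, "n1_length", NA_character_),
                            path, "n1_length"),
      n2_len = .parse_count(.opt_col(tab, "n2_length", NA_character_),
                            path, "n2_length"),
      productive = toupper(tab$productive) %in% c("T", "TRUE", "1"),
      mean_quality = .parse_count(.opt_col(tab, "consensus_quality",
                                           NA_character_),
                                  path, "consensus_quality")
    )
  } else {
    v_call <- .mixcr_first_hit(tab$allVHitsWithScore)
    aa <- tab$aaSeqCDR3
    rec <- tibble::tibble(
      sample_id = sample_id,
      v_call = v_call,
      v_gene = normalize_ighv(v_call),
      d_gene = .mixcr_first_hit(tab$allDHitsWithScore),
      j_gene = .mixcr_first_hit(tab$allJHitsWithScore),
      cdr3_aa = aa,
      cdr3_nt = tab$nSeqCDR3,
      read_count = .parse_count(tab$cloneCount, path, "cloneCount"),
      n1_len = .parse_count(.opt_col(tab, "nLengthVDJunction", NA_character_),
                            path, "nLengthVDJunction"),
      n2_len = .parse_count(.opt_col(tab, "nLengthDJJunction", NA_character_),
                            path, "nLengthDJJunction"),
      # MiXCR tables carry no explicit productivity flag; out-of-frame or
      # stop-containing junctions are marked in the aa sequence itself
      productive = !grepl("[*_]", aa),
      mean_quality = .parse_count(.opt_col(tab, "avrgQualCDR3", NA_character_),
                                  path, "avrgQualCDR3")
    )
  }
  .validate_records(rec, path)
  rec
}

.validate_records <- function(rec, context = "records") {
  if (nrow(rec) == 0L) return(invisible(rec))
  if (any(is.na(rec$cdr3_aa) | !nzchar(rec$cdr3_aa))) {
    stop(context, ": empty cdr3_aa", call. = FALSE)
  }
  if (any(rec$read_count < 0, na.rm = TRUE)) {
    stop(context, ": negative read_count", call. = FALSE)
  }
  if (any(rec$n1_len < 0 | rec$n2_len < 0, na.rm = TRUE)) {
    stop(context, ": negative junction N-length", call. = FALSE)
  }
  both <- !is.na(rec$cdr3_nt) & !is.na(rec$cdr3_aa)
  if (any(nchar(rec$cdr3_nt[both]) != 3L * nchar(rec$cdr3_aa[both]))) {
    stop(context, ": cdr3_nt length is not 3x cdr3_aa length", call. = FALSE)
  }
  invisible(rec)
}

#' QC-filter clone records
#'
#' Drops records whose mean CDR3 quality is below `min_quality` (records
#' with no quality annotation pass) and non-functional records (stop codon
#' `*` in the CDR3, or `productive == FALSE` when `require_productive`).
#'
#' @param records Clone-record tibble from [read_clone_table()].
#' @param min_quality Phred threshold, default 30 (Q30).
#' @param require_productive Drop records flagged non-productive.
#' @return A list with `kept` (filtered tibble) and `rejected` (tibble of
#'   `sample_id`, `cdr3_aa`, `reason`).
#' @export
filter_records <- function(records, min_quality = 30,
                           require_productive = TRUE) {
  stopifnot(min_quality >= 0)
  if (nrow(records) == 0L) {
    return(list(kept = records,
                rejected = tibble::tibble(sample_id = character(0),
                                          cdr3_aa = character(0),
                                          reason = character(0))))
  }
  low_q <- !is.na(records$mean_quality) & records$mean_quality < min_quality
  nonfunc <- grepl("*", records$cdr3_aa, fixed = TRUE) |
    (require_productive & !records$productive)
  reason <- dplyr::case_when(
    low_q   ~ sprintf("quality<Q%g", min_quality),
    nonfunc ~ "non-functional",
    TRUE    ~ NA_character_
  )
  drop <- !is.na(reason)
  list(
    kept = records[!drop, , drop = FALSE],
    rejected = tibble::tibble(sample_id = records$sample_id[drop],
                              cdr3_aa = records$cdr3_aa[drop],
                              reason = reason[drop])
  )
}

#' Aggregate clone records into a repertoire
#'
#' Merges records with identical CDR3 amino-acid sequence into one
#' clonotype: read counts are summed; gene labels (and nucleotide sequence,
#' junction N-lengths) are taken by majority vote weighted by read count,
#' ties broken lexicographically. Clone fractions are computed against the
#' summed read count of the sample.
#'
#' @param records Clone-record tibble (all rows of one sample).
#' @param sample_id Sample identifier; defaults to the records' common id.
#' @param organ One of `"SPL"`, `"LN"`, `"blood"`, `"PC"`, `"BM"`.
#' @return An object of class `repertoire`: a list with `sample_id`,
#'   `organ`, `total_reads` and `clones`, a tibble with one row per distinct
#'   `cdr3_aa` carrying a `fraction` column summing to 1.
#' @export
aggregate_repertoire <- function(records, sample_id = NULL, organ = "SPL") {
  organ <- match.arg(organ, c("SPL", "LN", "blood", "PC", "BM"))
  if (is.null(sample_id)) {
    ids <- unique(records$sample_id)
    if (length(ids) > 1L) {
      stop("records span several sample_ids: ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    sample_id <- if (length(ids)) ids else NA_character_
  }
  total <- sum(records$read_count)
  if (!isTRUE(total > 0)) {
    stop("empty repertoire: total read count is 0 for sample ",
         sample_id, call. = FALSE)
  }
  majority <- function(val, wt) {
    ok <- !is.na(val)
    if (!any(ok)) return(val[1])
    s <- tapply(wt[ok], val[ok], sum)
    names(s)[order(-s, names(s))][1]
  }
  majority_num <- function(val, wt) {
    ok <- !is.na(val)
    if (!any(ok)) return(val[1])
    s <- tapply(wt[ok], val[ok], sum)
    as.numeric(names(s)[order(-s, as.numeric(names(s)))][1])
  }
  clones <- records |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(
      v_call = majority(.data$v_call, .data$read_count),
      v_gene = majority(.data$v_gene, .data$read_count),
      d_gene = majority(.data$d_gene, .data$read_count),
      j_gene = majority(.data$j_gene, .data$read_count),
      cdr3_nt = majority(.data$cdr3_nt, .data$read_count),
      read_count = sum(.data$read_count),
      n1_len = majority_num(.data$n1_len, .data$read_count),
      n2_len = majority_num(.data$n2_len, .data$read_count),
      productive = all(.data$productive),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$read_count / total) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$cdr3_aa)
  structure(
    list(sample_id = sample_id, organ = organ,
         total_reads = total, clones = clones),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s (%s): %d clonotypes, %s reads, top fraction %.3f\n",
              x$sample_id, x$organ, nrow(x$clones),
              format(x$total_reads, big.mark = ","),
              max(x$clones$fraction)))
  invisible(x)
}

#' Write a repertoire back to a clone table
#'
#' Round-trip counterpart of [read_clone_table()]: `read(write(r))`
#' reproduces clonotypes, counts and gene labels exactly.
#'
#' @param repertoire A `repertoire` object.
#' @param path Output TSV path.
#' @param dialect `"airr"` or `"mixcr"`.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(repertoire, path, dialect = c("airr", "mixcr")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(repertoire, "repertoire"))
  cl <- repertoire$clones
  if (dialect == "airr") {
    out <- tibble::tibble(
      sample_id = repertoire$sample_id,
      junction_aa = cl$cdr3_aa,
      junction = cl$cdr3_nt,
      v_call = cl$v_call,
      d_call = cl$d_gene,
      j_call = cl$j_gene,
      duplicate_count = cl$read_count,
      productive = ifelse(cl$productive, "T", "F"),
      n1_length = cl$n1_len,
      n2_length = cl$n2_len
    )
  } else {
    out <- tibble::tibble(
      sample_id = repertoire$sample_id,
      cloneCount = cl$read_count,
      aaSeqCDR3 = cl$cdr3_aa,
      nSeqCDR3 = cl$cdr3_nt,
      allVHitsWithScore = cl$v_call,
      allDHitsWithScore = cl$d_gene,
      allJHitsWithScore = cl$j_gene,
      nLengthVDJunction = cl$n1_len,
      nLengthDJJunction = cl$n2_len
    )
  }
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
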