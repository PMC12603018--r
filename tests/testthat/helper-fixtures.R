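# Small in-code fixtures shared across test files.

# a clone-record tibble in the package's canonical internal form
make_records <- function(cdr3_aa, read_count,
                         v_call = "IGHV1-55*01",
                         sample_id = "S1",
                         d_gene = "IGHD2-1", j_gene = "IGHJ1",
                         n1_len = 2, n2_len = 2,
                         productive = TRUE, mean_quality = 35,
                         cdr3_nt = NA_character_) {
  n <- length(cdr3_aa)
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    v_call = rep_len(v_call, n),
    v_gene = normalize_ighv(rep_len(v_call, n)),
    d_gene = rep_len(d_gene, n),
    j_gene = rep_len(j_gene, n),
    cdr3_aa = cdr3_aa,
    cdr3_nt = rep_len(cdr3_nt, n),
    read_count = rep_len(read_count, n),
    n1_len = rep_len(n1_len, n),
    n2_len = rep_len(n2_len, n),
    productive = rep_len(productive, n),
    mean_quality = rep_len(mean_quality, n)
  )
}

# a repertoire with the given clone fractions (counts scaled to 1e4 reads)
make_repertoire <- function(fractions, v_call = "IGHV1-55*01",
                            sample_id = "S1", organ = "SPL",
                            cdr3_aa = NULL) {
  if (is.null(cdr3_aa)) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    i <- seq_along(fractions) - 1L
    cdr3_aa <- paste0("CAR", aa[i %/% 20 + 1], aa[i %% 20 + 1], "GMDVW")
  }
  rec <- make_records(cdr3_aa, round(fractions * 1e4),
                      v_call = v_call, sample_id = sample_id)
  aggregate_repertoire(rec, sample_id, organ)
}

# random amino-acid string of the CDR3 alphabet
random_aa <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# write a minimal AIRR TSV and return its path
write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, na = "")
  path
}
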