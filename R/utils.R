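# Internal helpers shared across modules.

# Semicolon-joined integer / numeric fields are the on-disk and in-table
# representation of position sets and probability lists; "" means empty.

join_ints <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))

split_ints <- function(s) {
  lapply(strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.integer(v)
  })
}

split_nums <- function(s) {
  lapply(strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}

join_nums <- function(x, digits = 10) {
  vapply(x, function(v) paste(format(v, digits = digits, trim = TRUE, scientific = FALSE),
                              collapse = ";"), character(1))
}

# Canonical site identity: protein plus sorted 1-based positions.
site_id <- function(protein_id, positions_chr) paste0(protein_id, ":", positions_chr)

count_prolines <- function(sequence) {
  vapply(gregexpr("P", sequence, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) rlang::abort(msg)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
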