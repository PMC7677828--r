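# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_arg <- function(...) stop(..., call. = FALSE)

# deterministic child seed derived from a user seed and a stage tag;
# kept below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}

# haplotype bit-vector <-> string ("0"/"1" per site)
hap_to_string <- function(h) paste(as.integer(h), collapse = "")
string_to_hap <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1]])

hamming <- function(a, b) sum(a != b)
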