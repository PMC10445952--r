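## internal helpers shared across modules

## typed error helper: every user-facing failure carries a condition class
## so callers (and tests) can distinguish shape/coordinate/alphabet errors
mp_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mitopop_error")))
}

DNA_BASES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("-", "N")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  out <- comp[ch]
  if (anyNA(out)) stop("cannot reverse-complement characters: ",
                       paste(unique(ch[is.na(out)]), collapse = ", "))
  paste(out, collapse = "")
}

is_transition_pair <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

## paste a character matrix row-wise back into strings
rows_to_strings <- function(m) {
  if (ncol(m) == 0L) rep("", nrow(m)) else apply(m, 1L, paste, collapse = "")
}

seq_to_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]
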