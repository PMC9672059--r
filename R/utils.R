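# NA-safe blank coercion for character columns
blank_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# sample() that never falls into the 1:x trap on length-1 vectors
resample <- function(x, size = 1) {
  x[sample.int(length(x), size)]
}

# NA where blank
na_blank <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}
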