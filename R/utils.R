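# shared internal helpers: logging, RNG scoping, small sequence ops

.lox_log_level <- function() {
  lv <- getOption("loxscan.verbose", "info")
  match(lv, c("quiet", "info", "debug"), nomatch = 2L)
}

lox_log <- function(..., level = "info") {
  want <- match(level, c("quiet", "info", "debug"), nomatch = 2L)
  if (want <= .lox_log_level())
    message("[loxscan] ", ...)
  invisible(NULL)
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# plain string reversal (no complement)
str_rev <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

chrom_roman <- function(i) as.character(utils::as.roman(i))

# round half away from zero (CNV integerisation rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
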