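# Shared internal helpers.

# The 20 standard amino acids; 'X' is tolerated in input as "undefined residue".
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.assertAAString <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(.AA20, "X"))
  if (length(bad))
    stop(what, " contains invalid residue letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(seq)
}

.asCharacterSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) {
    x
  } else {
    stop("expected an AAStringSet or a named character vector of sequences",
         call. = FALSE)
  }
}

#' Derive a reproducible per-stage child seed from a global seed
#'
#' A single pipeline seed is fanned out to independent stage seeds by stable
#' hashing of the stage name, so any stage can be rerun in isolation and still
#' draw the same random stream it saw inside the full pipeline.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. \code{"proteome"}.
#' @return An integer seed below 2^31.
#' @export
#' @examples
#' stageSeed(1, "proteome")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) * 1000003 + h * 7919) %% 2147483629)
}

# Count occurrences of a single character in a string.
.countChar <- function(seq, ch) {
  lengths(regmatches(seq, gregexpr(ch, seq, fixed = TRUE)))
}
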