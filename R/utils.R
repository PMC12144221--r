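#' 32-bit FNV-1a hash of a character string
#'
#' Used to derive deterministic per-scan random substreams and to fingerprint
#' configurations. Arithmetic is done in double precision; all intermediates
#' stay below 2^53 so the result is exact.
#'
#' @param x a character scalar.
#' @return a non-negative integer-valued double < 2^32.
#' @keywords internal
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values (bitwXor is int-only)
bitwXor64 <- function(a, b) {
  r <- 0
  bit <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + bit
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Derive a named random substream seed
#'
#' All randomness in the package flows from one top-level seed; each unit of
#' work (a scan, a reader x scan pair) gets its own substream keyed by name,
#' so enlarging a study never perturbs the draws of existing scans.
#'
#' @param seed top-level integer seed.
#' @param name substream name, e.g. a scan id.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  as.integer((fnv1a32(name) + as.numeric(seed) * 2654435761) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  # Mersenne-Twister states seeded from nearby integers are poorly mixed
  # for the first few outputs; discard a short warm-up so substream draws
  # are unbiased.
  invisible(runif(20))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 8-hex-digit rendering of a 32-bit hash value held in a double
fnv1a32_hex <- function(h) {
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4),
         format(as.hexmode(as.integer(h %% 65536)), width = 4))
}

#' Write a table with a provenance comment line
#'
#' Every persisted table carries the configuration hash and seed on a leading
#' `#` comment line; [read_qc_table()] strips it again.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named list with elements `config_hash` and `seed`, or NULL.
#' @export
write_qc_table <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# phantomqc config_hash=%s seed=%s",
                       provenance$config_hash %||% "NA",
                       provenance$seed %||% "NA"), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qc_table
#' @export
read_qc_table <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

round1 <- function(x) round(x, 1)
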