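# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a child seed from a base seed and a stream index; stays in 32-bit range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483587)
}

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("metatrait_format_error", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(sprintf(...), class = c("metatrait_domain_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as TSV with full double precision and "NA" sentinels
write_tsv_precise <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }
  })
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(fmt, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}
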