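## Internal helpers: classed conditions, seeded RNG scopes, small parsers.

plStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "plError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

plFormatError <- function(fmt, ...) plStop("plFormatError", fmt, ...)
plLookupError <- function(fmt, ...) plStop("plLookupError", fmt, ...)
plDomainError <- function(fmt, ...) plStop("plDomainError", fmt, ...)
plUsageError  <- function(fmt, ...) plStop("plUsageError", fmt, ...)
plConfigError <- function(fmt, ...) plStop("plConfigError", fmt, ...)
plLoadError   <- function(fmt, ...) plStop("plLoadError", fmt, ...)

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
## Fixed kinds make output a pure function of the seed across platforms.
withSeed <- function(seed, expr) {
  env <- globalenv()
  hadSeed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = env)
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

## Read a TSV with '#' comment lines and a header, tolerating extra columns.
readTsv <- function(path) {
  lines <- readInput(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(data.frame())
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## Accept a file path or raw text (single string with newlines or a
## character vector of lines); return a character vector of lines.
readInput <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

## Pick the first matching column name; NA if absent.
pickColumn <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

joinSet <- function(x) paste(sort(unique(x)), collapse = ";")

splitSet <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

## Canonical JSON used for all on-disk reports: stable key order is the
## caller's responsibility; serialization options are fixed here so that a
## recomputed report is byte-identical to a stored one.
toCanonicalJSON <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

writeCanonicalJSON <- function(x, path) {
  writeLines(as.character(toCanonicalJSON(x)), path)
  invisible(path)
}
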