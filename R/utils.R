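# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

# resolve an input that is either a file path or literal text into a
# connection-ready argument for read.delim (file() is gzip-transparent)
.tsvInput <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text))
    stop("provide either 'file' or 'text'")
  if (!is.null(text)) return(list(text = text))
  if (!file.exists(file)) stop("file not found: ", file)
  list(file = file)
}

.readTsv <- function(file = NULL, text = NULL, header = TRUE) {
  inp <- .tsvInput(file, text)
  args <- c(inp, list(sep = "\t", header = header, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE))
  tryCatch(do.call(read.delim, args),
           error = function(e) {
             # empty file / header-only
             data.frame()
           })
}
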