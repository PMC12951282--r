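# internal helpers shared across modules

# round half away from zero (embedded-style), as opposed to R's banker round
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# duration in ms -> whole samples at rate fs, nearest integer
msToSamples <- function(ms, fs) as.integer(round(fs * ms / 1000))

# run expr with a local RNG state; seed = NULL leaves the global state alone
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# empty canonical spike-event table
emptyEvents <- function() {
  data.frame(electrode = character(0), t_sample = integer(0),
             t_ms = numeric(0), amplitude_uV = numeric(0),
             detector = character(0), stringsAsFactors = FALSE)
}

# validate/normalize an event table: required columns, sorted by time
asEvents <- function(events) {
  need <- c("electrode", "t_ms")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop("event table must contain at least columns: ",
         paste(need, collapse = ", "))
  if (is.unsorted(events$t_ms)) events <- events[order(events$t_ms), ]
  events
}

# atomic write: run writer(tmp), then rename onto path
atomicWrite <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
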