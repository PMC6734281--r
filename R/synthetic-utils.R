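#' Deterministic child seeds for per-generator random streams
#'
#' Every generator draws from its own stream, derived from the scenario
#' seed and a tag, so adding a generator never perturbs the others.
#' @param seed integer master seed
#' @param tag character stream tag
#' @return an integer seed below 2^31
#' @export
child_seed <- function(seed, tag) {
  h <- 0
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147480000
  as.integer((as.numeric(seed) * 7919 + h + 1) %% 2147480000)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# subtract a set of intervals from [0, L); returns data.frame(start, end)
free_segments <- function(L, exclude = NULL) {
  if (is.null(exclude) || nrow(exclude) == 0) {
    return(data.frame(start = 0, end = L))
  }
  ex <- exclude[order(exclude$start), , drop = FALSE]
  segs <- list()
  cur <- 0
  for (i in seq_len(nrow(ex))) {
    s <- max(0, ex$start[i]); e <- min(L, ex$end[i])
    if (s > cur) segs[[length(segs) + 1]] <- c(cur, s)
    cur <- max(cur, e)
  }
  if (cur < L) segs[[length(segs) + 1]] <- c(cur, L)
  out <- do.call(rbind, segs)
  data.frame(start = out[, 1], end = out[, 2])
}
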