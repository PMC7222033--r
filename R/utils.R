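#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

empty_ivmat <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

# Coerce exon/CDS segment input (matrix, data.frame, list of c(start,end),
# or a single c(start,end)) into a sorted integer matrix.
as_ivmat <- function(x) {
  if (is.null(x)) return(empty_ivmat())
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- cbind(x[[1L]], x[[2L]])
  } else if (is.list(x)) {
    if (!length(x)) return(empty_ivmat())
    m <- do.call(rbind, lapply(x, function(e) as.integer(e[1:2])))
  } else if (is.numeric(x) && length(x) == 2L) {
    m <- matrix(as.integer(x), ncol = 2L)
  } else {
    stop("cannot interpret interval input")
  }
  m <- matrix(as.integer(m), ncol = 2L)
  colnames(m) <- c("start", "end")
  if (!nrow(m)) return(empty_ivmat())
  if (any(is.na(m)) || any(m[, 2L] < m[, 1L]) || any(m[, 1L] < 1L))
    stop("invalid interval: start must be >= 1 and end >= start")
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

iv_width <- function(m) if (nrow(m)) sum(m[, 2L] - m[, 1L] + 1L) else 0L

# Merge overlapping or book-ended intervals (base-set union).
iv_reduce <- function(m) {
  if (nrow(m) < 2L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  ks <- integer(nrow(m)); ke <- integer(nrow(m)); n <- 0L
  cs <- m[1L, 1L]; ce <- m[1L, 2L]
  for (i in 2:nrow(m)) {
    if (m[i, 1L] <= ce + 1L) {
      ce <- max(ce, m[i, 2L])
    } else {
      n <- n + 1L; ks[n] <- cs; ke[n] <- ce
      cs <- m[i, 1L]; ce <- m[i, 2L]
    }
  }
  n <- n + 1L; ks[n] <- cs; ke[n] <- ce
  out <- cbind(start = ks[seq_len(n)], end = ke[seq_len(n)])
  out
}

# Number of shared bases between two interval sets (sorted-merge sweep).
iv_intersect_width <- function(a, b) {
  a <- iv_reduce(a); b <- iv_reduce(b)
  if (!nrow(a) || !nrow(b)) return(0L)
  i <- 1L; j <- 1L; w <- 0L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1L], b[j, 1L]); e <- min(a[i, 2L], b[j, 2L])
    if (e >= s) w <- w + (e - s + 1L)
    if (a[i, 2L] < b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  w
}

# TRUE when every base of `x` lies within the base-union of `outer`.
iv_contains <- function(outer, x) {
  xr <- iv_reduce(x)
  iv_intersect_width(outer, xr) == iv_width(xr)
}

# All (query index, subject index) overlap pairs between two interval vectors.
iv_hits <- function(qs, qe, ss, se, maxgap = -1L) {
  if (!length(qs) || !length(ss))
    return(data.frame(q = integer(0), s = integer(0)))
  h <- findOverlaps(IRanges(qs, qe), IRanges(ss, se), maxgap = maxgap)
  data.frame(q = queryHits(h), s = subjectHits(h))
}

# Connected components from an edge list over 1..n; returns component labels
# renumbered 1..k in order of first member.
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- root(edges[k, 1L]); rj <- root(edges[k, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  lab <- vapply(seq_len(n), root, integer(1))
  match(lab, unique(lab))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

dot_or <- function(x, fmt = NULL) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(".")
  if (!is.null(fmt)) sprintf(fmt, x) else as.character(x)
}
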