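#' @importFrom stats median rbinom rlnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Run code under a caller-supplied seed without clobbering the global RNG
## stream. seed = NULL means "use the current stream".
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a parent seed; kept inside 32-bit integer range.
childSeed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483563) + 1L
}

isDNA <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

## Hamming distance between two equal-length strings.
hammingDist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Pairwise Hamming distance matrix for equal-length strings, computed
## column-by-column on the character matrix (blocked to bound memory).
hammingMatrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  L <- unique(nchar(x))
  stopifnot(length(L) == 1L)
  m <- matrix(unlist(strsplit(x, ""), use.names = FALSE), nrow = n, byrow = TRUE)
  D <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    D <- D + outer(m[, j], m[, j], "!=")
  }
  D
}

## Union-find with path compression; returns component id per element.
unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1L])
      rj <- find(pairs[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

genotypeDose <- function(gt) {
  doses <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  bad <- !(gt %in% names(doses))
  if (any(bad))
    stop("unknown genotype(s): ", paste(unique(gt[bad]), collapse = ", "),
         " (expected 0/0, 0/1 or 1/1)", call. = FALSE)
  unname(doses[gt])
}
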