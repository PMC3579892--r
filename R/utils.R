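#' @importFrom rlang abort warn %||%
#' @importFrom stats cor median mad sd quantile rnorm runif rexp rbinom
#' @importFrom stats hclust cutree as.dist kmeans ecdf pchisq runmed
#' @importFrom stats fisher.test kruskal.test pt setNames
#' @importFrom utils head tail
NULL

# Expand one user seed into named child seeds so that adding a generator
# call never perturbs the draws of an earlier one.
child_seeds <- function(seed, components) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  draws <- sample.int(.Machine$integer.max - 1L, length(components))
  setNames(draws, components)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# 1 - Pearson correlation distance between the columns of `x`.
# Columns with zero variance have no defined correlation; name the offender.
pearson_dist <- function(x) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant sample vector(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", "),
                 "; Pearson correlation is undefined"))
  }
  as.dist(1 - cor(x))
}

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) abort(paste0(what, " must be a numeric matrix"))
  if (anyNA(x) || any(!is.finite(x))) abort(paste0(what, " contains missing or non-finite values"))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort(paste0(what, " must carry gene rownames and sample colnames"))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 means identical up to renaming, 0 is the expectation under independent
#' random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
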