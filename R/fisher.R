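#' Vectorised two-sided Fisher's exact test for 2x2 tables
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities no
#' larger than that of the observed table (with the conventional 1 + 1e-7
#' relative tolerance), plus the sample odds ratio. Vectorised over tables;
#' repeated tables are computed once.
#'
#' @param a,b,c,d Cell counts: table rows are `(a, b)` and `(c, d)`.
#' @return `data.frame` with columns `p` and `odds_ratio` (sample odds
#'   ratio `a*d / (b*c)`, possibly `Inf` or `NaN` for empty margins).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n,
            all(c(a, b, c, d) >= 0))
  key <- paste(a, b, c, d)
  uniq <- !duplicated(key)
  pu <- vapply(which(uniq), function(i) {
    .fisher_p_one(a[i], b[i], c[i], d[i])
  }, 0)
  p <- pu[match(key, key[uniq])]
  data.frame(p = p, odds_ratio = (a * d) / (b * c))
}

.fisher_p_one <- function(a, b, c, d) {
  m <- a + b   # row 1 total ("white")
  n2 <- c + d  # row 2 total ("black")
  k <- a + c   # column 1 total (drawn)
  if (m + n2 == 0L || k == 0L || k == m + n2) return(1)
  support <- max(0L, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
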