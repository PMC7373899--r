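# Shared toy problems and small fixture builders.

# linear-Gaussian regression objective: y = a + b x + noise; the objective is
# the exact -2 log L (up to constant), so profiles are analytic parabolas and
# Wald intervals are exact.
toy_linear_gaussian <- function(n = 30, a = 1, b = 2, sigma = 0.5,
                                seed = 42) {
  set.seed(seed)
  x <- seq(-1, 1, length.out = n)
  y <- a + b * x + rnorm(n, 0, sigma)
  obj <- function(theta) sum((y - theta[1] - theta[2] * x)^2) / sigma^2
  fit <- lm(y ~ x)
  list(obj = obj, x = x, y = y, sigma = sigma,
       coef = coef(fit), se = sqrt(diag(vcov(fit))) * sigma /
         summary(fit)$sigma)
}

# quadratic objective in delta with selected informative coordinates: emulates
# a data objective whose minimizer is delta_true with unit curvature `curv`
toy_delta_objective <- function(delta_true, curv = 200) {
  function(delta) curv * sum((delta - delta_true)^2)
}

# brute-force IUPAC scan used as the independent oracle for motif matching
iupac_table <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))
brute_scan <- function(seq_chr, pattern, both_strands = TRUE) {
  seq_chr <- toupper(seq_chr); pattern <- toupper(pattern)
  revcomp <- function(s) chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  match_at <- function(s, p, pos) {
    for (i in seq_len(nchar(p))) {
      sc <- substr(s, pos + i - 1, pos + i - 1)
      pc <- substr(p, i, i)
      # subject N matches only when the pattern position allows any base
      ok <- if (sc == "N") length(iupac_table[[pc]]) == 4
            else sc %in% iupac_table[[pc]]
      if (!ok) return(FALSE)
    }
    TRUE
  }
  hits <- NULL
  pats <- list(c(pattern, "+"))
  if (both_strands) pats <- c(pats, list(c(revcomp(pattern), "-")))
  L <- nchar(seq_chr); m <- nchar(pattern)
  for (ps in pats) for (pos in seq_len(max(L - m + 1, 0)))
    if (match_at(seq_chr, ps[1], pos))
      hits <- rbind(hits, data.frame(start = pos - 1L, end = pos - 1L + m,
                                     strand = ps[2]))
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0),
                                strand = character(0)) else
    hits[order(hits$start, hits$strand), ]
}
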