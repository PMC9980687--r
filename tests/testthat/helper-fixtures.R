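# shared fixture builders (everything generated in code, no data files)

# DreamSet from a bare methylation matrix; constant coverage unless given
toyDreamSet <- function(m, coverage = 200L, colData = NULL) {
    if (is.null(rownames(m)))
        rownames(m) <- paste0("chr1:", seq_len(nrow(m)) * 10L)
    if (is.null(colnames(m)))
        colnames(m) <- paste0("s", seq_len(ncol(m)))
    cv <- if (is.matrix(coverage)) coverage else
        matrix(as.integer(coverage), nrow(m), ncol(m),
               dimnames = dimnames(m))
    DreamSet(m, cv, rownames(m), colData)
}

# exact (expectation-valued, rounded) spike-in counts at digestion
# efficiency cTrue; mirrors the read-level signature probability
exactSpikes <- function(cTrue, depth = 10000L,
                        levels = seq(0, 100, 12.5),
                        sample_id = "s1") {
    m <- levels / 100
    p <- ifelse(m <= 0, 0, ifelse(m >= 1, 1, m / (m + cTrue * (1 - m))))
    X <- round(depth * p)
    data.frame(standard_id = sprintf("std%02d", seq_along(levels)),
               expected_meth = levels, n_meth = as.integer(X),
               n_unmeth = as.integer(depth - X), sample_id = sample_id,
               stringsAsFactors = FALSE)
}

# stochastic spike-ins for one sample
randomSpikes <- function(cTrue, depth = 10000L,
                         levels = seq(0, 100, 12.5),
                         sample_id = "s1") {
    m <- levels / 100
    p <- ifelse(m <= 0, 0, ifelse(m >= 1, 1, m / (m + cTrue * (1 - m))))
    X <- rbinom(length(levels), depth, p)
    data.frame(standard_id = sprintf("std%02d", seq_along(levels)),
               expected_meth = levels, n_meth = X,
               n_unmeth = depth - X, sample_id = sample_id,
               stringsAsFactors = FALSE)
}

# two-group DreamSet with Gaussian methylation around group means
twoGroupDreamSet <- function(muRef, muExp, n = 6L, sd = 3,
                             coverage = 200L) {
    k <- length(muRef)
    mr <- matrix(rnorm(k * n, muRef, sd), k, n)
    me <- matrix(rnorm(k * n, muExp, sd), k, n)
    m <- pmin(pmax(cbind(mr, me), 0.1), 99.9)
    colnames(m) <- c(paste0("ref", seq_len(n)), paste0("exp", seq_len(n)))
    rownames(m) <- paste0("chr1:", seq_len(k) * 10L)
    toyDreamSet(m, coverage)
}

refCols <- function(x) grep("^ref", colnames(x), value = TRUE)
expCols <- function(x) grep("^exp", colnames(x), value = TRUE)
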