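# Gaussian-emission HMM machinery behind the structural alphabet:
# Viterbi encoding, Baum-Welch training and BIC model-size selection.

.defaultLetterNames <- function(K) {
  pool <- c("a", LETTERS, setdiff(letters, "a"))
  if (K <= length(pool)) pool[seq_len(K)] else sprintf("s%02d", seq_len(K))
}

# Evaluate expr with a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Log density of rows of X under N(mean, cov); cholesky-based, d = 4.
.mvnLogDensity <- function(X, mean, cov) {
  R <- chol(cov)
  Z <- forwardsolve(t(R), t(X) - mean)
  -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

.descriptorMatrix <- function(descriptors) {
  if (is.data.frame(descriptors))
    descriptors <- as.matrix(descriptors[, c("d13", "d14", "d24", "h")])
  descriptors <- as.matrix(descriptors)
  stopifnot(ncol(descriptors) == 4L)
  descriptors
}

# n x K matrix of per-letter emission log densities.
.emissionLogDens <- function(X, model) {
  K <- length(model@letters)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    out[, k] <- .mvnLogDensity(X, model@emissionMean[k, ], model@emissionCov[, , k])
  out
}

#' Encode a descriptor sequence into structural letters
#'
#' Maximum a posteriori encoding: given the 4-D descriptors of consecutive
#' four-residue fragments, returns the jointly most probable letter path
#' under the alphabet's hidden Markov model (Viterbi algorithm in log
#' space).  An unbroken trace of `n` residues yields `n - 3` descriptors
#' and hence `n - 3` letters.  Ties are broken towards the lowest letter
#' index, so the result is deterministic.
#'
#' @param descriptors matrix or data.frame of descriptors, columns
#'   `d13`, `d14`, `d24`, `h`, one row per fragment, in order.
#' @param model an [AlphabetModel-class].
#' @return a single string of structural letters, one per descriptor row.
#' @seealso [encodeStructure()] to go directly from a C-alpha trace.
#' @export
encodeDescriptors <- function(descriptors, model) {
  X <- .descriptorMatrix(descriptors)
  if (nrow(X) == 0L) stop("descriptors must be non-empty")
  bad <- which(!is.finite(rowSums(X)))
  if (length(bad))
    stop(sprintf("non-finite descriptor value in window(s) %s",
                 paste(bad, collapse = ", ")))
  validObject(model)
  K <- length(model@letters)
  logB <- .emissionLogDens(X, model)
  logA <- log(model@transition)
  n <- nrow(X)
  delta <- log(model@initial) + logB[1L, ]
  psi <- matrix(0L, n, K)
  if (n > 1L) {
    for (t in 2:n) {
      cand <- delta + logA               # K x K: cand[i, j] = delta[i] + logA[i, j]
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  paste(model@letters[path], collapse = "")
}

#' Encode a C-alpha trace into structural-letter sequences
#'
#' Computes fragment descriptors with [computeDescriptors()] (chain breaks
#' split the trace) and Viterbi-encodes each contiguous descriptor run
#' independently.
#'
#' @inheritParams computeDescriptors
#' @param model an [AlphabetModel-class].
#' @return a data.frame with one row per segment: `protein_id`,
#'   `chain_id`, `segment`, `letters` (the encoded string), `anchor` (row
#'   index in `trace` of the first letter's fragment) and `resno_start`.
#' @examples
#' \dontrun{
#' seqs <- encodeStructure(readCaTraces("file.pdb")[[1]], model)
#' }
#' @export
encodeStructure <- function(trace, model, maxCaGap = 4.5) {
  desc <- computeDescriptors(trace, maxCaGap)
  segs <- split(desc, desc$segment)
  out <- lapply(segs, function(d) {
    data.frame(protein_id = trace$protein_id[1L], chain_id = trace$chain_id[1L],
               segment = d$segment[1L],
               letters = encodeDescriptors(d, model),
               anchor = d$anchor[1L], resno_start = d$resno[1L],
               stringsAsFactors = FALSE)
  })
  res <- .rbindRows(out)
  if (is.null(res))
    res <- data.frame(protein_id = character(0), chain_id = character(0),
                      segment = integer(0), letters = character(0),
                      anchor = integer(0), resno_start = integer(0))
  res
}

.asCorpusList <- function(corpus) {
  if (!is.list(corpus) || is.data.frame(corpus)) corpus <- list(corpus)
  lapply(corpus, .descriptorMatrix)
}

# One scaled forward-backward + M-step sufficient statistics pass over a
# batch of equal-length sequences.  obs: list over time of S x 4 matrices is
# avoided; instead X is (S*T) x 4 in sequence-major order.
.ebatch <- function(X, S, T, init, trans, means, covs) {
  K <- length(init)
  logB <- matrix(0, S * T, K)
  for (k in seq_len(K)) logB[, k] <- .mvnLogDensity(X, means[k, ], covs[, , k])
  idx <- function(t) seq.int(t, by = T, length.out = S)   # rows of time t
  rowsMax <- apply(logB, 1L, max)
  Bs <- exp(logB - rowsMax)

  alpha <- vector("list", T)
  ct <- matrix(0, S, T)
  a <- Bs[idx(1L), , drop = FALSE] * rep(init, each = S)
  ct[, 1L] <- rowSums(a)
  alpha[[1L]] <- a / ct[, 1L]
  if (T > 1L) for (t in 2:T) {
    a <- (alpha[[t - 1L]] %*% trans) * Bs[idx(t), , drop = FALSE]
    ct[, t] <- rowSums(a)
    alpha[[t]] <- a / ct[, t]
  }
  if (any(!is.finite(ct)) || any(ct <= 0)) stop("numerical underflow in E-step")
  ll <- sum(log(ct)) + sum(rowsMax)

  gamma <- matrix(0, S * T, K)
  xi <- matrix(0, K, K)
  beta <- matrix(1, S, K)
  gamma[idx(T), ] <- alpha[[T]]
  if (T > 1L) for (t in (T - 1L):1L) {
    Bb <- Bs[idx(t + 1L), , drop = FALSE] * beta / ct[, t + 1L]
    xi <- xi + crossprod(alpha[[t]], Bb) * trans
    beta <- Bb %*% t(trans)
    g <- alpha[[t]] * beta
    gamma[idx(t), ] <- g / rowSums(g)
  }
  list(ll = ll, gamma = gamma, xi = xi, gamma1 = colSums(gamma[idx(1L), , drop = FALSE]))
}

.bwFit <- function(seqs, K, init, trans, means, covs, reg, maxit, tol) {
  lens <- vapply(seqs, nrow, 1L)
  byLen <- split(seq_along(seqs), lens)
  # sequence-major stacked observations per length group
  stacks <- lapply(byLen, function(ix) do.call(rbind, seqs[ix]))
  llTrace <- numeric(0)
  for (iter in seq_len(maxit)) {
    ll <- 0
    gammaSum <- 0
    xSum <- matrix(0, K, 4L)
    xi <- matrix(0, K, K)
    g1 <- numeric(K)
    gammas <- vector("list", length(stacks))
    for (gi in seq_along(stacks)) {
      T <- as.integer(names(byLen))[gi]
      S <- length(byLen[[gi]])
      e <- .ebatch(stacks[[gi]], S, T, init, trans, means, covs)
      ll <- ll + e$ll
      gammas[[gi]] <- e$gamma
      gammaSum <- gammaSum + colSums(e$gamma)
      xSum <- xSum + crossprod(e$gamma, stacks[[gi]])
      xi <- xi + e$xi
      g1 <- g1 + e$gamma1
    }
    llTrace <- c(llTrace, ll)
    if (any(gammaSum < 1e-8)) stop("empty state during EM")
    means <- xSum / gammaSum
    for (k in seq_len(K)) {
      Sk <- matrix(0, 4L, 4L)
      for (gi in seq_along(stacks)) {
        Xc <- t(stacks[[gi]]) - means[k, ]
        Sk <- Sk + Xc %*% (t(Xc) * gammas[[gi]][, k])
      }
      covs[, , k] <- Sk / gammaSum[k] + diag(reg, 4L)
    }
    if (K > 1L) {
      rs <- rowSums(xi)
      if (any(rs <= 0)) stop("empty transition row during EM")
      trans <- xi / rs
    }
    init <- g1 / sum(g1)
    if (iter > 1L && abs(llTrace[iter] - llTrace[iter - 1L]) <
          tol * (1 + abs(llTrace[iter]))) break
  }
  list(init = init, trans = trans, means = means, covs = covs,
       logLik = llTrace[length(llTrace)], llTrace = llTrace)
}

.kmeansInit <- function(seqs, K, reg) {
  X <- do.call(rbind, seqs)
  # Lloyd on large samples may stop at iter.max; the clustering only
  # seeds the EM, so full convergence is not required
  km <- suppressWarnings(kmeans(X, centers = K, nstart = 2L,
                                iter.max = 100L, algorithm = "Lloyd"))
  means <- km$centers
  covs <- array(0, c(4L, 4L, K))
  pooled <- cov(X) * (nrow(X) - 1) / nrow(X)
  for (k in seq_len(K)) {
    Xk <- X[km$cluster == k, , drop = FALSE]
    covs[, , k] <- if (nrow(Xk) >= 8L)
      cov(Xk) * (nrow(Xk) - 1) / nrow(Xk) + diag(reg + 1e-4, 4L)
    else pooled + diag(reg + 1e-4, 4L)
  }
  trans <- matrix(1, K, K)
  init <- rep(1, K)
  pos <- 0L
  for (s in seqs) {
    lab <- km$cluster[pos + seq_len(nrow(s))]
    pos <- pos + nrow(s)
    init[lab[1L]] <- init[lab[1L]] + 1
    if (length(lab) > 1L)
      for (t in seq_len(length(lab) - 1L))
        trans[lab[t], lab[t + 1L]] <- trans[lab[t], lab[t + 1L]] + 1
  }
  list(init = init / sum(init), trans = trans / rowSums(trans),
       means = means, covs = covs)
}

#' Train a structural alphabet by Baum-Welch
#'
#' Fits a `K`-state hidden Markov model with full-covariance Gaussian
#' emissions over 4-D fragment descriptors.  Each of `restarts` runs is
#' initialised from a k-means clustering of the pooled descriptors (hard
#' labels seed the transition counts) and iterated to convergence; the run
#' with the best log-likelihood wins.  Covariances are ridge-regularised
#' by `reg * I` at every M-step.  Runs that collapse (empty state,
#' singular covariance, underflow) are discarded and retried; if every
#' restart fails an error is raised.  The fit is reproducible given
#' `seed` and leaves the caller's RNG stream untouched.
#'
#' For `K = 1` the fit reduces to the closed form: the pooled maximum
#' likelihood mean and covariance (plus `reg * I`) and a trivial
#' transition matrix.
#'
#' @param corpus a list of descriptor sequences (matrices or data.frames
#'   with columns `d13`, `d14`, `d24`, `h`), or a single such matrix.
#' @param K number of structural letters (>= 1).
#' @param seed integer seed controlling the k-means initialisations.
#' @param restarts number of independent initialisations (default 5).
#' @param reg ridge added to each emission covariance (default 1e-6).
#' @param maxit,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param letterNames optional letter names (default `a`, `A`-`Z` order).
#' @return an [AlphabetModel-class] (all letters classed `loop`; see
#'   [assignLetterClasses()]), with attributes `logLik`, `logLikTrace`
#'   (per-iteration log-likelihoods of the winning run) and `nobs`.
#' @export
trainAlphabet <- function(corpus, K, seed = 1L, restarts = 5L, reg = 1e-6,
                          maxit = 100L, tol = 1e-8, letterNames = NULL) {
  seqs <- .asCorpusList(corpus)
  stopifnot(K >= 1L, all(vapply(seqs, nrow, 1L) >= 1L))
  nobs <- sum(vapply(seqs, nrow, 1L))
  if (nobs < 10L * K)
    stop(sprintf("need at least %d observations to fit K = %d letters", 10L * K, K))
  best <- NULL
  errors <- character(0)
  for (r in seq_len(restarts)) {
    fit <- tryCatch(.withSeed(seed * 1000L + r, {
      ini <- .kmeansInit(seqs, K, reg)
      .bwFit(seqs, K, ini$init, ini$trans, ini$means, ini$covs, reg, maxit, tol)
    }), error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  if (is.null(best))
    stop("all restarts failed: ", paste(unique(errors), collapse = "; "))
  lets <- if (is.null(letterNames)) .defaultLetterNames(K) else letterNames
  model <- AlphabetModel(lets, best$means, best$covs,
                         if (K == 1L) matrix(1, 1, 1) else best$trans,
                         best$init)
  attr(model, "logLik") <- best$logLik
  attr(model, "logLikTrace") <- best$llTrace
  attr(model, "nobs") <- nobs
  model
}

#' Select the alphabet size by BIC
#'
#' Fits [trainAlphabet()] for each candidate `K` and scores the fits with
#' the Bayesian Information Criterion
#' `BIC = -2 logL + p log(N)` where `N` is the total number of descriptor
#' observations and `p = (K - 1) + K (K - 1) + 14 K` counts the free
#' initial, transition and Gaussian (4 mean + 10 covariance) parameters.
#'
#' @inheritParams trainAlphabet
#' @param K_values integer vector of candidate alphabet sizes.
#' @param ... passed on to [trainAlphabet()].
#' @return a list with `bestK` (the BIC-minimising size) and `table`, a
#'   data.frame of `K`, `logLik`, `p`, `BIC` (NA rows for sizes whose fit
#'   failed).
#' @export
selectAlphabetSize <- function(corpus, K_values, seed = 1L, ...) {
  seqs <- .asCorpusList(corpus)
  nobs <- sum(vapply(seqs, nrow, 1L))
  rows <- lapply(K_values, function(K) {
    fit <- tryCatch(trainAlphabet(seqs, K, seed = seed, ...),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(K = K, logLik = NA_real_, p = NA_real_, BIC = NA_real_))
    p <- (K - 1) + K * (K - 1) + K * 14
    data.frame(K = K, logLik = attr(fit, "logLik"), p = p,
               BIC = -2 * attr(fit, "logLik") + p * log(nobs))
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$BIC))) stop("no alphabet size could be fitted")
  list(bestK = tab$K[which.min(tab$BIC)], table = tab)
}

#' Assign secondary-structure classes to structural letters
#'
#' Labels each letter `helix` or `strand` when the Mahalanobis distance
#' (under the letter's own emission covariance) between its emission mean
#' and the corresponding reference descriptor falls below `tol`; all other
#' letters are classed `loop`.  Reference descriptors default to the ideal
#' helix and strand geometries of the synthetic backbone generator.
#' Classes read from an alphabet model file are authoritative and should
#' not be overwritten by this function.
#'
#' @param model an [AlphabetModel-class].
#' @param helixRef,strandRef length-4 reference descriptors
#'   (`d13`, `d14`, `d24`, `h`).
#' @param tol Mahalanobis distance threshold in standard-deviation units
#'   (default 3).
#' @return the model with `letterClasses` updated.
#' @export
assignLetterClasses <- function(model,
                                helixRef = helixReferenceDescriptor(),
                                strandRef = strandReferenceDescriptor(),
                                tol = 3) {
  K <- length(model@letters)
  cls <- character(K)
  for (k in seq_len(K)) {
    S <- model@emissionCov[, , k]
    dh <- sqrt(mahalanobis(matrix(model@emissionMean[k, ], 1L), helixRef, S))
    ds <- sqrt(mahalanobis(matrix(model@emissionMean[k, ], 1L), strandRef, S))
    cls[k] <- if (dh < tol && dh <= ds) "helix"
              else if (ds < tol) "strand"
              else "loop"
  }
  letterClasses(model) <- cls
  model
}

#' @importFrom stats mahalanobis
NULL
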