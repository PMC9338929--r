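#' Reference expression profile per cell type
#'
#' @slot profile matrix X (genes x types): mean expression of each type
#'   over its reference cells (on the linear library-scaled layer by
#'   default), restricted to the genes shared with the ST data.
#' @slot cellsByType named list mapping each type to its member reference
#'   cell ids.
#' @export
setClass("ReferenceProfile",
  representation(profile = "matrix", cellsByType = "list")
)

setValidity("ReferenceProfile", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@profile), names(object@cellsByType)))
    msg <- c(msg, "profile columns and cellsByType names must match")
  if (any(lengths(object@cellsByType) < 1))
    msg <- c(msg, "every type needs at least one reference cell")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile:", nrow(object@profile), "genes x",
      ncol(object@profile), "cell types\n")
})

#' @describeIn ReferenceProfile-class the genes x types mean profile.
#' @param x a \linkS4class{ReferenceProfile}.
#' @export
referenceProfile <- function(x) {
  stopifnot(is(x, "ReferenceProfile"))
  x@profile
}

#' Build the per-type mean reference profile
#'
#' Averages the expression of the labeled reference cells within each
#' cell type, on the genes shared with the ST data. The default layer is
#' the library-size-scaled linear layer (\code{\link{linearLayer}}): the
#' spot-equals-sum-of-cells mixing model is additive on that scale,
#' whereas a log transform breaks additivity and biases mixtures toward
#' uniform.
#'
#' @param ref reference scRNA-seq as an \linkS4class{STData}.
#' @param labels named character vector: reference cell id -> cell type.
#'   Every reference cell must be labeled and at least 2 types present.
#' @param stGenes optional character vector of ST genes; the profile is
#'   restricted to the intersection (>= 2 shared genes required).
#' @param layer \code{"linear"} (default): library-size-scaled counts,
#'   on which the mixing model is additive; or \code{"lognorm"}: the
#'   log-normalized layer.
#' @param scaleFactor per-cell total for the linear scaling.
#' @return a \linkS4class{ReferenceProfile}.
#' @export
buildReferenceProfile <- function(ref, labels, stGenes = NULL,
                                  layer = c("linear", "lognorm"),
                                  scaleFactor = 1e4) {
  layer <- match.arg(layer)
  stopifnot(is(ref, "STData"))
  cells <- unitNames(ref)
  if (!all(cells %in% names(labels))) {
    stop("unlabeled reference cell(s): ",
         paste(utils::head(setdiff(cells, names(labels)), 5), collapse = ", "))
  }
  labels <- labels[cells]
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types in the reference")
  if (layer == "lognorm" && is.null(assayLogcounts(ref))) {
    ref <- logNormalize(ref, scaleFactor)
  }
  genes <- geneNames(ref)
  if (!is.null(stGenes)) {
    genes <- intersect(genes, stGenes)
    if (length(genes) < 2) stop("fewer than 2 genes shared with the ST data")
  }
  lg <- if (layer == "linear") {
    linearLayer(ref, scaleFactor)[genes, , drop = FALSE]
  } else {
    assayLogcounts(ref)[genes, , drop = FALSE]
  }
  cellsByType <- split(cells, labels)[types]
  X <- vapply(types, function(tp) {
    sub <- lg[, cellsByType[[tp]], drop = FALSE]
    Matrix::rowSums(sub) / ncol(sub)
  }, numeric(length(genes)))
  dimnames(X) <- list(genes, types)
  new("ReferenceProfile", profile = X, cellsByType = cellsByType)
}

# Mean relative-entropy loss per unit: mean_g( y log(y/yhat) - y + yhat ),
# 0 log 0 = 0, yhat floored.
.klLossPerUnit <- function(Y, Yhat, ylogy_colsum, ycolsum) {
  n <- nrow(Y)
  Yhat <- pmax(Yhat, 1e-12)
  cross <- colSums(Y * log(Yhat))
  (ylogy_colsum - cross - ycolsum + colSums(Yhat)) / n
}

#' Fit the non-negative linear deconvolution model
#'
#' Solves, independently per unit, \code{argmin_{beta >= 0} L(Y - X beta)}
#' where L is the mean relative-entropy (KL) loss, plus optional L1,
#' angle, and L2 regularization terms (weights default 0), using
#' multiplicative updates until convergence or an iteration cap.
#'
#' @param Y numeric matrix (genes x units) or vector of unit expression
#'   on the same genes and layer as the reference profile.
#' @param X a \linkS4class{ReferenceProfile} or a genes x types matrix.
#' @param config a \linkS4class{RunConfig}; \code{maxIter}, \code{tol}
#'   and the lambda weights are used.
#' @param rawCounts optional raw count matrix aligned with \code{Y}, used
#'   for the expressed-gene "unsure" floor; when absent the nonzero count
#'   of \code{Y} itself is used.
#' @return a \linkS4class{Composition} with raw weights, proportions, a
#'   per-unit convergence flag, the loss trace, and the unsure mask.
#' @examples
#' X <- cbind(A = c(4, 1, 0), B = c(0, 1, 4))
#' rownames(X) <- paste0("G", 1:3)
#' y <- X %*% c(0.7, 0.3)
#' compositionProps(fitNNLM(y, X))
#' @export
fitNNLM <- function(Y, X, config = runConfig(), rawCounts = NULL) {
  if (is(X, "ReferenceProfile")) X <- referenceProfile(X)
  if (is.null(dim(Y))) {
    Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "unit1"))
  }
  Y <- as.matrix(Y)
  if (!is.null(rownames(Y)) && !is.null(rownames(X))) {
    shared <- intersect(rownames(Y), rownames(X))
    if (length(shared) < 2) stop("fewer than 2 shared genes")
    Y <- Y[shared, , drop = FALSE]
    X <- X[shared, , drop = FALSE]
  }
  if (any(Y < 0) || any(X < 0)) stop("negative values in Y or X")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("unit", seq_len(ncol(Y)))

  # genes the reference cannot explain at all carry no information
  zeroRow <- rowSums(X) == 0
  if (any(zeroRow)) {
    if (any(Y[zeroRow, , drop = FALSE] > 0)) {
      warning(sum(zeroRow), " gene(s) with all-zero reference profile dropped")
    }
    Y <- Y[!zeroRow, , drop = FALSE]
    X <- X[!zeroRow, , drop = FALSE]
  }
  k <- ncol(X)
  s <- ncol(Y)
  n <- nrow(Y)
  types <- colnames(X)
  if (is.null(types)) types <- paste0("type", seq_len(k))

  exprGenes <- if (!is.null(rawCounts)) {
    colSums(as.matrix(rawCounts) > config@minExpr)
  } else {
    colSums(Y > 0)
  }
  zeroUnit <- colSums(Y) == 0
  unsure <- zeroUnit | exprGenes < config@minGenes

  B <- matrix(0, k, s, dimnames = list(types, colnames(Y)))
  conv <- rep(TRUE, s)
  names(conv) <- colnames(Y)
  trace <- numeric(0)
  act <- which(!zeroUnit)
  if (length(act)) {
    Ya <- Y[, act, drop = FALSE]
    ycolsum <- colSums(Ya)
    ylogy <- Ya * log(pmax(Ya, 1e-300))
    ylogy[Ya == 0] <- 0
    ylogy_colsum <- colSums(ylogy)
    Ba <- matrix(rep(ycolsum / max(sum(X), 1e-12), each = k), k,
                 length(act))
    Xt <- t(X)
    xcol <- colSums(X)
    l1 <- config@lambda1; l2 <- config@lambda2; la <- config@lambdaAlpha
    lossOld <- .klLossPerUnit(Ya, X %*% Ba, ylogy_colsum, ycolsum)
    trace <- mean(lossOld)
    convA <- rep(FALSE, length(act))
    it <- 0L
    while (it < config@maxIter) {
      nstep <- min(10L, config@maxIter - it)
      for (i in seq_len(nstep)) {
        Yhat <- pmax(X %*% Ba, 1e-12)
        num <- Xt %*% (Ya / Yhat)
        den <- xcol + l1 + l2 * Ba +
          la * (matrix(rep(colSums(Ba), each = k), k) - Ba)
        Ba <- Ba * as.matrix(num) / pmax(den, 1e-12)
        it <- it + 1L
      }
      lossNew <- .klLossPerUnit(Ya, X %*% Ba, ylogy_colsum, ycolsum)
      trace <- c(trace, mean(lossNew))
      convA <- convA |
        abs(lossNew - lossOld) / pmax(abs(lossOld), 1e-12) < config@tol
      lossOld <- lossNew
      if (all(convA)) break
    }
    conv[act] <- convA
    B[, act] <- Ba
  }
  tot <- colSums(B)
  P <- B
  pos <- tot > 0
  P[, pos] <- sweep(B[, pos, drop = FALSE], 2, tot[pos], "/")
  new("Composition", weights = B, props = P, converged = conv,
      lossTrace = trace, unsureMask = unname(unsure))
}

#' Assign cell-type labels to single-cell resolution ST units
#'
#' The type with the maximum fitted coefficient is assigned to each cell;
#' cells flagged unsure or whose maximum proportion is below
#' \code{unsurePropMin} are labeled \code{"unsure"}. Exact ties are
#' broken toward the lexicographically first type and flagged.
#'
#' @param comp a \linkS4class{Composition} from a single-cell mode fit.
#' @param config a \linkS4class{RunConfig}.
#' @return \code{data.frame} with columns \code{unit}, \code{type},
#'   \code{max_prop}, \code{ambiguous}.
#' @export
assignCellLabels <- function(comp, config = runConfig()) {
  P <- compositionProps(comp)
  types <- sort(rownames(P))
  P <- P[types, , drop = FALSE]
  mx <- apply(P, 2, max)
  lab <- types[apply(P, 2, which.max)]
  amb <- colSums(P == rep(mx, each = nrow(P))) > 1 & mx > 0
  unsure <- unsureMask(comp) | mx < config@unsurePropMin
  lab[unsure] <- "unsure"
  data.frame(unit = colnames(P), type = lab, max_prop = unname(mx),
             ambiguous = unname(amb), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Integer cell counts per type for one spot
#'
#' Rounds \code{M * beta} half-up per type; if the rounded counts exceed
#' the spot capacity M, types with the smallest fractional parts are
#' decremented (ties toward the lexicographically first type) until the
#' total equals M. A nonzero spot whose counts all round to zero gets one
#' cell of its maximum-proportion type.
#'
#' @param beta named non-negative proportion vector summing to 1.
#' @param M maximum cells in the spot (>= 1).
#' @param spotNonzero whether the spot has any expression (controls the
#'   all-zero floor rule).
#' @return named integer vector omega with \code{sum(omega) <= M}.
#' @examples
#' spotCellCombination(c(A = 0.52, B = 0.48), M = 30)  # 16, 14
#' @export
spotCellCombination <- function(beta, M, spotNonzero = TRUE) {
  stopifnot(M >= 1, all(beta >= 0))
  if (is.null(names(beta))) names(beta) <- paste0("type", seq_along(beta))
  origOrder <- names(beta)
  beta <- beta[order(names(beta))]
  mb <- M * beta
  fr <- mb - floor(mb)
  om <- as.integer(floor(mb) + (fr >= 0.5))
  names(om) <- names(beta)
  dec <- integer(length(om))
  while (sum(om) > M) {
    cand <- which(om > 0)
    # smallest fractional part first; spread over types before hitting
    # the same type again; remaining ties by type name
    victim <- cand[order(dec[cand], fr[cand], names(om)[cand])][1]
    om[victim] <- om[victim] - 1L
    dec[victim] <- dec[victim] + 1L
  }
  if (sum(om) == 0 && spotNonzero && any(beta > 0)) {
    om[which.max(beta)] <- 1L
  }
  om[origOrder]
}

#' Select reference cells realizing a spot's cellular combination
#'
#' Over \code{nRestarts} random draws of \code{omega[i]} reference cells
#' per type i (with replacement when a type has fewer members), keeps the
#' draw whose merged log-normalized profile minimizes the squared error
#' against the spot profile.
#'
#' @param spotY named numeric vector: the spot's log-normalized profile.
#' @param omega named integer vector from
#'   \code{\link{spotCellCombination}}.
#' @param ref reference \linkS4class{STData} (log normalization applied
#'   if absent).
#' @param labels named character vector: reference cell -> type.
#' @param config a \linkS4class{RunConfig} (\code{nRestarts}).
#' @return list with \code{cells} (chosen reference cell ids, one entry
#'   per placed cell), \code{types} (their types), \code{fitError} (the
#'   minimized squared error), \code{omega}.
#' @export
selectSpotCells <- function(spotY, omega, ref, labels,
                            config = runConfig()) {
  stopifnot(is(ref, "STData"))
  omega <- omega[omega > 0]
  if (length(omega) == 0) {
    return(list(cells = character(0), types = character(0),
                fitError = sum(spotY^2), omega = omega))
  }
  if (is.null(assayLogcounts(ref))) ref <- logNormalize(ref)
  genes <- intersect(names(spotY), geneNames(ref))
  lg <- assayLogcounts(ref)[genes, , drop = FALSE]
  y <- spotY[genes]
  cellsByType <- split(unitNames(ref), labels[unitNames(ref)])
  missing <- setdiff(names(omega), names(cellsByType))
  if (length(missing)) {
    stop("cell type(s) absent from reference: ",
         paste(missing, collapse = ", "))
  }
  R <- config@nRestarts
  m <- sum(omega)
  # draws[ , r] = reference column indices of the r-th candidate set
  draws <- matrix(0L, m, R)
  rowAt <- 1L
  for (tp in names(omega)) {
    pool <- match(cellsByType[[tp]], unitNames(ref))
    w <- omega[[tp]]
    repl <- length(pool) < w
    d <- replicate(R, if (length(pool) == 1L) rep(pool, w) else
      sample(pool, w, replace = repl))
    draws[rowAt:(rowAt + w - 1L), ] <- d
    rowAt <- rowAt + w
  }
  # merged profile per draw via a sparse selection matrix
  sel <- Matrix::sparseMatrix(i = as.vector(draws),
                              j = rep(seq_len(R), each = m),
                              x = 1, dims = c(ncol(lg), R))
  merged <- as.matrix(lg %*% sel)
  sse <- colSums((merged - y)^2)
  best <- which.min(sse)
  idx <- draws[, best]
  list(cells = unitNames(ref)[idx],
       types = rep(names(omega), times = omega),
       fitError = sse[best], omega = omega)
}
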