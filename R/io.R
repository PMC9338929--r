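#' Read a gene x unit expression matrix
#'
#' Supported formats: a delimited table (genes in rows, first column or
#' rownames giving gene symbols, remaining columns units) or
#' matrix-market triplet (\code{.mtx}) accompanied by one-symbol-per-line
#' row (gene) and column (unit) name files.
#'
#' Gene-symbol hygiene follows standard practice for count matrices:
#' duplicated symbols are removed entirely (every copy) with a message
#' giving the count, and when an alias table is supplied, symbols are
#' first remapped through it and symbols missing from the table dropped
#' as unmatched. By default no remapping is attempted.
#'
#' @param path file path. For matrix-market, the \code{.mtx} file;
#'   row/column names are read from \code{rowPath}/\code{colPath}.
#' @param format \code{"delimited"} or \code{"mtx"}.
#' @param sep field separator for delimited input (default tab).
#' @param rowPath,colPath name files for matrix-market input; default
#'   \code{<path>.rownames} / \code{<path>.colnames}.
#' @param aliasFile optional two-column table (\code{alias},
#'   \code{symbol}) used to revise gene symbols before deduplication.
#' @return an \linkS4class{STData} with the raw layer only.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(matrix(1:6, 3, 2, dimnames = list(paste0("G", 1:3),
#'   paste0("U", 1:2))), f, sep = "\t", quote = FALSE)
#' readExpression(f)
#' @export
readExpression <- function(path, format = c("delimited", "mtx"), sep = "\t",
                           rowPath = paste0(path, ".rownames"),
                           colPath = paste0(path, ".colnames"),
                           aliasFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    # read without row.names so duplicated gene symbols survive parsing
    # (they are removed below, per standard count-matrix hygiene)
    head2 <- readLines(path, n = 2)
    h <- strsplit(head2[1], sep, fixed = TRUE)[[1]]
    d <- strsplit(head2[2], sep, fixed = TRUE)[[1]]
    if (length(h) == length(d) - 1) {
      tab <- utils::read.table(path, header = FALSE, sep = sep, skip = 1,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
      colnames(tab) <- c(".gene", h)
    } else {
      tab <- utils::read.table(path, header = TRUE, sep = sep,
                               check.names = FALSE, row.names = NULL,
                               stringsAsFactors = FALSE)
    }
    genes <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
    bad <- which(!vapply(tab, is.numeric, logical(1)))
    if (length(bad)) {
      stop("non-numeric expression values in column(s): ",
           paste(colnames(tab)[utils::head(bad, 5)], collapse = ", "))
    }
    m <- as.matrix(tab)
    rownames(m) <- genes
  } else {
    if (!file.exists(rowPath) || !file.exists(colPath)) {
      stop("matrix-market input needs name files: ", rowPath, ", ", colPath)
    }
    m <- Matrix::readMM(path)
    rn <- readLines(rowPath)
    cn <- readLines(colPath)
    if (nrow(m) != length(rn)) {
      stop("triplet row dimension (", nrow(m),
           ") does not match gene name list (", length(rn), ")")
    }
    if (ncol(m) != length(cn)) {
      stop("triplet column dimension (", ncol(m),
           ") does not match unit name list (", length(cn), ")")
    }
    dimnames(m) <- list(rn, cn)
  }
  if (any(m < 0)) stop("negative counts in ", path)
  m <- .cleanGeneSymbols(m, aliasFile)
  STData(m)
}

.cleanGeneSymbols <- function(m, aliasFile = NULL) {
  genes <- rownames(m)
  if (!is.null(aliasFile)) {
    al <- utils::read.table(aliasFile, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("alias", "symbol") %in% colnames(al))) {
      stop("alias file must have columns 'alias' and 'symbol'")
    }
    idx <- match(genes, al$alias)
    unmatched <- is.na(idx)
    if (any(unmatched)) {
      message(sum(unmatched), " unmatched gene symbol(s) removed")
      m <- m[!unmatched, , drop = FALSE]
      idx <- idx[!unmatched]
    }
    rownames(m) <- al$symbol[idx]
    genes <- rownames(m)
  }
  dup <- genes %in% genes[duplicated(genes)]
  if (any(dup)) {
    warning(sum(dup), " row(s) with duplicated gene symbols removed (",
            length(unique(genes[dup])), " symbol(s))")
    m <- m[!dup, , drop = FALSE]
  }
  m
}

#' Write an expression matrix as a delimited table
#'
#' @param x an \linkS4class{STData}.
#' @param path output path. @param sep separator. @param layer which layer.
#' @export
writeExpression <- function(x, path, sep = "\t",
                            layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  m <- if (layer == "raw") assayCounts(x) else assayLogcounts(x)
  if (is.null(m)) stop("layer ", layer, " not present")
  utils::write.table(as.matrix(m), path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Global-scaling log normalization
#'
#' Scales each unit (column) to a common total count, then applies the
#' natural log of 1 + value. All-zero units are left all-zero with a
#' warning and should be treated as unsure downstream.
#'
#' @param x an \linkS4class{STData} with a raw layer.
#' @param scaleFactor the common per-unit total (default 10000).
#' @return the same \linkS4class{STData} with the \code{lognorm} layer
#'   filled in; the raw layer is retained.
#' @examples
#' m <- matrix(c(10, 0, 5, 5), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("U1", "U2")))
#' assayLogcounts(logNormalize(STData(m), scaleFactor = 10))
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  stopifnot(is(x, "STData"), scaleFactor > 0)
  cnt <- assayCounts(x)
  tot <- Matrix::colSums(cnt)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero unit(s) left unnormalized")
  }
  scl <- ifelse(zero, 0, scaleFactor / pmax(tot, 1e-300))
  lg <- cnt
  # dgCMatrix: scale the nonzero entries column-wise, then log1p
  if (length(lg@x)) {
    colIdx <- rep.int(seq_len(ncol(lg)), diff(lg@p))
    lg@x <- log1p(lg@x * scl[colIdx])
  }
  new("STData", counts = cnt, logcounts = lg, coords = x@coords)
}

#' Library-size-scaled linear expression layer
#'
#' Scales each unit's counts to a common total without a log transform.
#' The additive mixing model behind deconvolution (a spot's profile is the
#' sum of its member cells' profiles) holds on this scale, so it is the
#' default layer for the non-negative fit; all-zero units stay zero.
#'
#' @param x an \linkS4class{STData}.
#' @param scaleFactor the common per-unit total (default 10000).
#' @return dense genes x units matrix.
#' @export
linearLayer <- function(x, scaleFactor = 1e4) {
  stopifnot(is(x, "STData"))
  cnt <- assayCounts(x)
  tot <- Matrix::colSums(cnt)
  scl <- ifelse(tot == 0, 0, scaleFactor / pmax(tot, 1e-300))
  out <- cnt
  if (length(out@x)) {
    colIdx <- rep.int(seq_len(ncol(out)), diff(out@p))
    out@x <- out@x * scl[colIdx]
  }
  as.matrix(out)
}

#' Read unit coordinates
#'
#' @param path delimited file with three columns: unit id, x, y (header
#'   optional; detected from the first line).
#' @param sep separator.
#' @return \code{data.frame} with columns \code{x}, \code{y} and unit ids
#'   as rownames.
#' @export
readCoordinates <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  tab <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("coordinate file needs 3 columns (unit, x, y)")
  tab <- tab[, 1:3]
  colnames(tab) <- c("unit", "x", "y")
  if (anyDuplicated(tab$unit)) {
    stop("duplicated unit id(s) in coordinates: ",
         paste(utils::head(unique(tab$unit[duplicated(tab$unit)]), 5),
               collapse = ", "))
  }
  if (!is.numeric(tab$x) || !is.numeric(tab$y) ||
      any(!is.finite(tab$x)) || any(!is.finite(tab$y))) {
    stop("non-numeric or non-finite coordinates in ", path)
  }
  out <- data.frame(x = tab$x, y = tab$y, row.names = as.character(tab$unit))
  out
}

#' Parse a GMT gene-set file
#'
#' @param path GMT file: per line, set name, description, then member
#'   genes, tab-separated.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load the prior knowledge base
#'
#' Reads the ligand-receptor pair table, the pathway knowledge, and the
#' transcription-factor list, normalizes symbol case, and deduplicates.
#'
#' @param lriPath delimited table with columns \code{ligand} and
#'   \code{receptor} (extra columns ignored; multi-subunit entries
#'   written as \code{A_B} are split into per-gene rows).
#' @param pathwayPath pathway knowledge as either a 3-column directed
#'   edge list (\code{src}, \code{dest}, \code{source}) or a GMT file
#'   (detected by the \code{.gmt} extension). GMT sets contribute
#'   membership sets for enrichment; edge lists additionally define the
#'   knowledge-graph wiring.
#' @param tfPath plain text, one TF symbol per line.
#' @param uppercase normalize all symbols to upper case (default TRUE,
#'   the human-symbol convention).
#' @return a \linkS4class{PriorKnowledge}.
#' @export
readPriorKnowledge <- function(lriPath, pathwayPath = NULL, tfPath = NULL,
                               uppercase = TRUE) {
  norm <- if (uppercase) toupper else identity
  lri <- utils::read.table(lriPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(lri))) {
    stop("LRI table must have columns 'ligand' and 'receptor'")
  }
  # split multi-subunit complexes (A_B) into per-gene rows
  rows <- do.call(rbind, lapply(seq_len(nrow(lri)), function(i) {
    expand.grid(ligand = strsplit(lri$ligand[i], "_", fixed = TRUE)[[1]],
                receptor = strsplit(lri$receptor[i], "_", fixed = TRUE)[[1]],
                stringsAsFactors = FALSE)
  }))
  rows$ligand <- norm(rows$ligand)
  rows$receptor <- norm(rows$receptor)
  rows <- unique(rows[rows$ligand != rows$receptor, , drop = FALSE])
  rownames(rows) <- NULL

  pw <- data.frame(src = character(0), dest = character(0),
                   source = character(0), stringsAsFactors = FALSE)
  psets <- list()
  if (!is.null(pathwayPath)) {
    if (grepl("\\.gmt$", pathwayPath, ignore.case = TRUE)) {
      psets <- lapply(readGMT(pathwayPath), norm)
    } else {
      pw <- utils::read.table(pathwayPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      if (ncol(pw) < 3) stop("pathway edge list needs 3 columns")
      colnames(pw)[1:3] <- c("src", "dest", "source")
      pw$src <- norm(pw$src)
      pw$dest <- norm(pw$dest)
      pw <- unique(pw[, c("src", "dest", "source")])
      rownames(pw) <- NULL
      # membership sets per source label, for enrichment tests
      psets <- lapply(split(pw, pw$source),
                      function(d) unique(c(d$src, d$dest)))
    }
  }
  tfs <- character(0)
  if (!is.null(tfPath)) {
    tfs <- unique(norm(trimws(readLines(tfPath))))
    tfs <- tfs[nzchar(tfs)]
  }
  new("PriorKnowledge", lri = rows, pathways = pw, tfs = tfs,
      pathwaySets = psets)
}

#' Attach coordinates to an expression matrix
#'
#' @param x an \linkS4class{STData}.
#' @param coords data.frame as returned by \code{\link{readCoordinates}}.
#' @return \linkS4class{STData} with coordinates; errors listing ids when
#'   the unit sets disagree.
#' @export
attachCoordinates <- function(x, coords) {
  STData(assayCounts(x), coords = coords, logcounts = assayLogcounts(x))
}
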