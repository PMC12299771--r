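#' Fingerprint configuration
#'
#' Settings for converting SMILES strings into fixed-length binary
#' fingerprint vectors. The representation is a hashed circular
#' (Morgan-type / ECFP) substructure fingerprint: atom-centred environments
#' up to `radius` bonds are hashed and folded onto `nBits` positions.
#'
#' @param nBits number of fingerprint bits (default 2048, minimum 8,
#'   maximum 4096 — the native hash width of the backend).
#' @param radius circular substructure radius in bonds (0 to 5, default 2;
#'   radius r corresponds to the ECFP\{2r\} diameter convention).
#' @param useChirality retain stereo annotations in the SMILES when
#'   parsing (default `TRUE`). When `FALSE`, stereo markers (`@`, `/`,
#'   `\`) are stripped first, so stereoisomeric spellings collapse onto
#'   one molecular graph. Note the circular-substructure hash itself is
#'   built from atom environments and may already be insensitive to
#'   tetrahedral chirality.
#' @return A list of class `fingerprintConfig`.
#' @examples
#' cfg <- fingerprintConfig(nBits = 1024, radius = 2)
#' @export
fingerprintConfig <- function(nBits = 2048L, radius = 2L, useChirality = TRUE) {
  nBits <- as.integer(nBits)
  radius <- as.integer(radius)
  stopifnot(length(nBits) == 1L, length(radius) == 1L)
  if (nBits < 8L || nBits > 4096L)
    stop("nBits must be in [8, 4096]")
  if (radius < 0L || radius > 5L)
    stop("radius must be in [0, 5]")
  structure(list(nBits = nBits, radius = radius,
                 useChirality = isTRUE(useChirality)),
            class = "fingerprintConfig")
}

# Quick syntactic screen: the backend parser silently truncates some
# malformed strings (e.g. unbalanced parentheses), so reject those up front.
validSmilesSyntax <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    return(FALSE)
  s <- trimws(smiles)
  if (!nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  TRUE
}

stripStereo <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

# Parse a batch of SMILES into backend molecule handles; returns a list or
# signals an error naming every failing row.
parseSmilesBatch <- function(smiles, useChirality = TRUE) {
  if (!useChirality) smiles <- vapply(smiles, stripStereo, character(1))
  bad <- which(!vapply(smiles, validSmilesSyntax, logical(1)))
  mols <- vector("list", length(smiles))
  for (i in setdiff(seq_along(smiles), bad)) {
    m <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smiles[[i]], identity)[[1]],
      error = function(e) NULL)
    if (is.null(m)) bad <- c(bad, i) else mols[[i]] <- m
  }
  if (length(bad))
    stop("unparsable SMILES at row(s): ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  mols
}

# Fold a native fingerprint row (counts over the backend's hash width) onto
# nBits binary positions by modular OR.
foldFingerprint <- function(native, nBits) {
  out <- integer(nBits)
  on <- which(native != 0) - 1L
  if (length(on)) out[unique(on %% nBits) + 1L] <- 1L
  out
}

ecfpName <- function(radius) sprintf("ECFP%d", 2L * radius)

# fingerprint_OB returns a vector for a single molecule and a matrix for a
# batch; normalize to one row per molecule.
nativeFingerprints <- function(mols, radius) {
  native <- ChemmineOB::fingerprint_OB(mols, ecfpName(radius))
  if (is.null(dim(native))) native <- matrix(native, nrow = 1L)
  native
}

#' Fingerprint a single SMILES string
#'
#' Deterministically converts one SMILES string into a binary fingerprint
#' vector of length `cfg$nBits`. Two SMILES spellings of the same molecule
#' yield bit-identical vectors (the backend canonicalizes the molecular
#' graph before hashing).
#'
#' @param smiles a single SMILES string.
#' @param cfg a [fingerprintConfig()].
#' @return Integer 0/1 vector of length `cfg$nBits`, named `bit_0000`, ...
#' @examples
#' fp <- featurizeSmiles("CCO", fingerprintConfig(nBits = 256))
#' sum(fp)
#' @export
featurizeSmiles <- function(smiles, cfg = fingerprintConfig()) {
  stopifnot(inherits(cfg, "fingerprintConfig"))
  mols <- parseSmilesBatch(smiles[1L], cfg$useChirality)
  native <- nativeFingerprints(mols, cfg$radius)
  out <- foldFingerprint(native[1L, ], cfg$nBits)
  names(out) <- defaultFeatureNames(cfg$nBits)
  out
}

#' Fingerprint a table of labeled molecules
#'
#' Converts a vector of SMILES with aligned class labels into a
#' [FeatureMatrix-class]. Row order is preserved; any unparsable SMILES
#' aborts the run with an error listing all offending rows (no silent
#' drops), keeping label/row alignment auditable.
#'
#' @param smiles character vector of SMILES strings (at least one).
#' @param labels class labels aligned with `smiles`.
#' @param cfg a [fingerprintConfig()].
#' @return A [FeatureMatrix-class] with `length(smiles)` rows and
#'   `cfg$nBits` columns named `bit_0000` ... .
#' @examples
#' tab <- fixtureSmiles()
#' fm <- featurizeTable(tab$smiles, tab$label, fingerprintConfig(nBits = 512))
#' dim(fm)
#' @export
featurizeTable <- function(smiles, labels, cfg = fingerprintConfig()) {
  stopifnot(inherits(cfg, "fingerprintConfig"))
  if (length(smiles) < 1L)
    stop("at least one molecule record is required")
  if (length(labels) != length(smiles))
    stop("labels must align with smiles")
  if (any(!nzchar(as.character(labels))) || anyNA(labels))
    stop("labels must be non-empty")
  mols <- parseSmilesBatch(smiles, cfg$useChirality)
  native <- nativeFingerprints(mols, cfg$radius)
  values <- t(apply(native, 1L, foldFingerprint, nBits = cfg$nBits))
  colnames(values) <- defaultFeatureNames(cfg$nBits)
  rownames(values) <- NULL
  FeatureMatrix(values, labels)
}

#' Read a molecule table from CSV
#'
#' Reads a UTF-8 comma-delimited file with a header row and columns
#' `smiles` and `label`.
#'
#' @param path file path.
#' @return data.frame with character columns `smiles` and `label`.
#' @export
readMoleculeCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("smiles", "label") %in% names(df)))
    stop("molecule CSV must have columns 'smiles' and 'label'")
  df[, c("smiles", "label")]
}

#' Write or read a feature matrix as CSV
#'
#' `writeFeatureCsv()` writes a [FeatureMatrix-class] either densely (one
#' row per molecule, feature columns plus a final `label` column) or as
#' sparse coordinate text (`row col value` triplets of the non-zero cells,
#' 1-based, with a `<path>.labels` sidecar file holding one label per row).
#' `readFeatureCsv()` reads the dense dialect back.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output/input file path.
#' @param sparse write sparse coordinate text instead of dense CSV.
#' @return `writeFeatureCsv()` returns `path` invisibly; `readFeatureCsv()`
#'   returns a [FeatureMatrix-class].
#' @export
writeFeatureCsv <- function(fm, path, sparse = FALSE) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- featureValues(fm)
  if (sparse) {
    nz <- which(X != 0, arr.ind = TRUE)
    df <- data.frame(row = nz[, 1], col = nz[, 2], value = X[nz])
    df <- df[order(df$row, df$col), ]
    utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                       sep = " ", quote = FALSE)
    writeLines(as.character(sampleLabels(fm)), paste0(path, ".labels"))
  } else {
    df <- as.data.frame(X)
    df$label <- as.character(sampleLabels(fm))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @param labelColumn name of the label column in a dense feature CSV.
#' @export
readFeatureCsv <- function(path, labelColumn = "label") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!labelColumn %in% names(df))
    stop("feature CSV must contain a '", labelColumn, "' column")
  labels <- df[[labelColumn]]
  X <- as.matrix(df[, setdiff(names(df), labelColumn), drop = FALSE])
  FeatureMatrix(X, labels)
}

#' Packaged example molecules
#'
#' Six labeled example molecules (two plastics, two peptides, two
#' oligosaccharides) shipped as a plain-text fixture, useful for smoke
#' tests of the featurization and prediction paths.
#'
#' @return data.frame with columns `smiles` and `label`.
#' @examples
#' fixtureSmiles()$label
#' @export
fixtureSmiles <- function() {
  path <- system.file("extdata", "example_smiles.csv", package = "polygru",
                      mustWork = TRUE)
  readMoleculeCsv(path)
}
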