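#' Genome table
#'
#' A genome is a named vector of chromosome lengths in base pairs.  All
#' coordinates in the package are 1-based and intervals are inclusive: an
#' event of length `L` starting at position `M` covers `[M, M + L - 1]`.
#'
#' @param lengths named numeric vector (or named list) of chromosome lengths
#'   in bp; names are chromosome identifiers.
#' @return An object of class `nco_genome`: a named numeric vector of
#'   chromosome lengths.
#' @examples
#' g <- nco_genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
nco_genome <- function(lengths) {
  lengths <- unlist(lengths)
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("chromosome lengths must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  names(lengths) <- nm
  structure(lengths, class = "nco_genome")
}

#' @export
print.nco_genome <- function(x, ...) {
  cat("Genome with", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read or write a genome TSV
#'
#' The file is tab-delimited with a header row and columns `chrom` and
#' `length`.
#'
#' @param path file path.
#' @return `read_genome()` returns an [nco_genome()] object;
#'   `write_genome()` returns `path` invisibly.
#' @export
read_genome <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "length"))
  len <- suppressWarnings(as.numeric(df$length))
  bad <- which(is.na(len))
  if (length(bad))
    stop("malformed length in ", path, " at data line ", bad[1])
  nco_genome(stats::setNames(len, df$chrom))
}

#' @rdname read_genome
#' @param genome an [nco_genome()] object.
#' @export
write_genome <- function(genome, path) {
  df <- data.frame(chrom = names(genome), length = format_pos(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Informative-marker map
#'
#' Positions of the quality-passing heterozygous (informative) markers of
#' each transmitting parent.  A gene conversion is only detectable at these
#' sites.  Each parent can be given a meiosis count: the number of
#' transmissions it contributes, used to weight parents when pooling the
#' detection function and to normalize event counts per meiosis.
#'
#' @param positions named list (one entry per parent) of named lists
#'   (one entry per chromosome) of integer marker positions.
#' @param meioses optional named numeric vector of per-parent meiosis
#'   counts; defaults to 1 per parent.
#' @param genome optional [nco_genome()]; if supplied, positions are checked
#'   against chromosome bounds.
#' @return An object of class `nco_markers`.
#' @export
nco_markers <- function(positions, meioses = NULL, genome = NULL) {
  if (!length(positions)) {
    warning("marker map is empty")
  }
  nm <- names(positions)
  if (length(positions) && (is.null(nm) || any(!nzchar(nm))))
    stop("marker positions must be a named list (one entry per parent)")
  positions <- lapply(positions, function(chrl) {
    cn <- names(chrl)
    if (length(chrl) && (is.null(cn) || any(!nzchar(cn))))
      stop("per-parent markers must be a named list (one entry per chromosome)")
    lapply(chrl, function(p) {
      p <- as.numeric(p)
      if (any(p < 1) || any(p != floor(p)))
        stop("marker positions must be positive integers")
      p <- sort(p)
      if (anyDuplicated(p))
        stop("duplicate marker position(s) within a parent-chromosome")
      p
    })
  })
  if (!is.null(genome)) {
    for (par in names(positions)) {
      for (chr in names(positions[[par]])) {
        if (!chr %in% names(genome))
          stop("unknown chromosome '", chr, "' for parent '", par, "'")
        p <- positions[[par]][[chr]]
        if (length(p) && max(p) > genome[[chr]])
          stop("marker position ", format_pos(max(p)), " beyond end of ",
               chr, " (length ", format_pos(genome[[chr]]), ")")
      }
    }
  }
  if (is.null(meioses)) {
    meioses <- stats::setNames(rep(1, length(positions)), names(positions))
  } else {
    meioses <- unlist(meioses)
    if (!all(names(positions) %in% names(meioses)))
      stop("meioses must be named with every parent id")
    meioses <- meioses[names(positions)]
    if (any(!is.finite(meioses)) || any(meioses <= 0))
      stop("meiosis counts must be positive")
  }
  structure(positions, meioses = meioses, class = "nco_markers")
}

#' @export
print.nco_markers <- function(x, ...) {
  nmk <- sum(vapply(x, function(ch) sum(lengths(ch)), 0))
  cat("Marker map:", length(x), "parent(s),", nmk, "informative marker(s),",
      sum(attr(x, "meioses")), "meiosis/es\n")
  invisible(x)
}

#' Read or write an informative-marker TSV
#'
#' Tab-delimited with header, columns `parent_id`, `chrom`, `pos` (1-based)
#' and optionally `meioses` (constant within a parent).
#'
#' @param path file path.
#' @param genome an [nco_genome()] used to validate positions.
#' @param meioses optional named per-parent meiosis counts, overriding any
#'   `meioses` column.
#' @return `read_markers()` returns an [nco_markers()] object.
#' @export
read_markers <- function(path, genome, meioses = NULL) {
  df <- read_tsv_checked(path, c("parent_id", "chrom", "pos"),
                         allow_empty = TRUE)
  if (!nrow(df)) {
    warning("marker file ", path, " is empty")
    return(suppressWarnings(
      nco_markers(stats::setNames(list(), character()), genome = genome)))
  }
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed position in ", path, " at data line ", bad[1])
  pos_by <- split(pos, list(df$parent_id, df$chrom), drop = TRUE)
  parents <- unique(df$parent_id)
  positions <- lapply(stats::setNames(parents, parents), function(par) {
    chroms <- unique(df$chrom[df$parent_id == par])
    lapply(stats::setNames(chroms, chroms),
           function(chr) pos_by[[paste(par, chr, sep = ".")]])
  })
  if (is.null(meioses) && "meioses" %in% names(df)) {
    meioses <- vapply(stats::setNames(parents, parents), function(par)
      as.numeric(df$meioses[df$parent_id == par][1]), 0)
  }
  nco_markers(positions, meioses = meioses, genome = genome)
}

#' @rdname read_markers
#' @param markers an [nco_markers()] object.
#' @export
write_markers <- function(markers, path) {
  rows <- list()
  mei <- attr(markers, "meioses")
  for (par in names(markers)) {
    for (chr in names(markers[[par]])) {
      p <- markers[[par]][[chr]]
      if (!length(p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = par, chrom = chr, pos = format_pos(p),
        meioses = format_pos(mei[[par]]))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(), chrom = character(),
               pos = character(), meioses = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene conversion tracts
#'
#' A tract is the non-empty set of gene-converted markers produced by a
#' single NCO event in one parent-offspring transmission.  Converted
#' positions need not be consecutive informative markers, but every one of
#' them must itself be an informative marker of the transmitting parent.
#'
#' @param tract_id character vector of unique tract identifiers.
#' @param parent_id character vector mapping each tract to a parent in the
#'   marker map.
#' @param chrom character vector of chromosome names.
#' @param positions list of strictly increasing integer vectors of converted
#'   marker positions (one per tract, each non-empty).
#' @param markers optional [nco_markers()]; if supplied, every converted
#'   position is checked to be an informative marker of that parent.
#' @return An object of class `nco_tracts` (a data frame with a list column
#'   `positions`).
#' @export
nco_tracts <- function(tract_id, parent_id, chrom, positions, markers = NULL) {
  tract_id <- as.character(tract_id)
  if (anyDuplicated(tract_id))
    stop("duplicate tract id(s): ",
         paste(unique(tract_id[duplicated(tract_id)]), collapse = ", "))
  if (length(parent_id) != length(tract_id) ||
      length(chrom) != length(tract_id) ||
      length(positions) != length(tract_id))
    stop("tract fields must have equal length")
  positions <- lapply(seq_along(positions), function(i) {
    p <- as.numeric(positions[[i]])
    if (!length(p))
      stop("tract '", tract_id[i], "' has no converted markers; ",
           "a tract is non-empty by definition")
    if (any(p < 1) || any(p != floor(p)))
      stop("tract '", tract_id[i], "': positions must be positive integers")
    p <- sort(p)
    if (anyDuplicated(p))
      stop("tract '", tract_id[i], "': duplicate converted position")
    p
  })
  if (!is.null(markers)) {
    for (i in seq_along(tract_id)) {
      par <- as.character(parent_id[i])
      if (!par %in% names(markers))
        stop("tract '", tract_id[i], "': unknown parent '", par, "'")
      mk <- markers[[par]][[as.character(chrom[i])]]
      p <- positions[[i]]
      idx <- findInterval(p, mk)
      missing <- p[idx < 1 | mk[pmax(idx, 1)] != p]
      if (length(missing))
        stop("tract '", tract_id[i], "': converted position(s) ",
             paste(format_pos(missing), collapse = ","),
             " are not informative markers of parent '", par,
             "' on ", chrom[i])
    }
  }
  df <- data.frame(tract_id = tract_id, parent_id = as.character(parent_id),
                   chrom = as.character(chrom), stringsAsFactors = FALSE)
  df$positions <- positions
  class(df) <- c("nco_tracts", "data.frame")
  df
}

#' Tract spans
#'
#' Span of a tract: distance in bp from its first to its last converted
#' marker, inclusive (`max - min + 1`).  A lower bound on the length of the
#' event that produced it.
#'
#' @param tracts an [nco_tracts()] object.
#' @return Integer vector of spans.
#' @export
tract_span <- function(tracts) {
  vapply(tracts$positions, function(p) max(p) - min(p) + 1, 0)
}

#' @export
print.nco_tracts <- function(x, ...) {
  cat("Gene conversion tracts:", nrow(x), "tract(s) in",
      length(unique(x$parent_id)), "parent(s); converted markers per tract ",
      min(lengths(x$positions)), "-", max(lengths(x$positions)),
      "; span ", min(tract_span(x)), "-", max(tract_span(x)), " bp\n",
      sep = "")
  invisible(x)
}

#' Read or write a tract TSV
#'
#' Tab-delimited with header, columns `tract_id`, `parent_id`, `chrom`,
#' `positions` where `positions` is a comma-separated list of converted
#' 1-based marker positions without spaces.
#'
#' @param path file path.
#' @param markers an [nco_markers()] object used for validation.
#' @return `read_tracts()` returns an [nco_tracts()] object.
#' @export
read_tracts <- function(path, markers) {
  df <- read_tsv_checked(path, c("tract_id", "parent_id", "chrom", "positions"))
  pos <- lapply(strsplit(df$positions, ",", fixed = TRUE), function(s) {
    p <- suppressWarnings(as.numeric(s[nzchar(s)]))
    if (any(is.na(p))) stop("malformed positions field in ", path)
    p
  })
  nco_tracts(df$tract_id, df$parent_id, df$chrom, pos, markers = markers)
}

#' @rdname read_tracts
#' @param tracts an [nco_tracts()] object.
#' @export
write_tracts <- function(tracts, path) {
  df <- data.frame(
    tract_id = tracts$tract_id, parent_id = tracts$parent_id,
    chrom = tracts$chrom,
    positions = vapply(tracts$positions,
                       function(p) paste(format_pos(p), collapse = ","), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a dataset
#'
#' Bundles genome, marker map and tracts, together with the total number of
#' meioses the tracts were collected from.
#'
#' @param genome an [nco_genome()].
#' @param markers an [nco_markers()].
#' @param tracts an [nco_tracts()].
#' @param n_meioses total number of meioses observed; defaults to the sum of
#'   the marker map's per-parent meiosis counts.
#' @return An object of class `nco_dataset`.
#' @export
nco_dataset <- function(genome, markers, tracts, n_meioses = NULL) {
  stopifnot(inherits(genome, "nco_genome"), inherits(markers, "nco_markers"),
            inherits(tracts, "nco_tracts"))
  unknown <- setdiff(unique(tracts$parent_id), names(markers))
  if (length(unknown))
    stop("tract parent id(s) missing from marker map: ",
         paste(unknown, collapse = ", "))
  if (is.null(n_meioses)) n_meioses <- sum(attr(markers, "meioses"))
  if (n_meioses < 1) stop("n_meioses must be >= 1")
  structure(list(genome = genome, markers = markers, tracts = tracts,
                 n_meioses = n_meioses), class = "nco_dataset")
}

#' @export
print.nco_dataset <- function(x, ...) {
  print(x$genome); print(x$markers); print(x$tracts)
  cat("Meioses:", x$n_meioses, "\n")
  invisible(x)
}

## -- internal helpers --------------------------------------------------------

# positions are written without scientific notation so files round-trip
format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

read_tsv_checked <- function(path, required, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", comment.char = "",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, " lacks required column(s): ", paste(missing, collapse = ", "))
  if (!nrow(df) && !allow_empty) stop(path, " contains no data rows")
  df
}
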