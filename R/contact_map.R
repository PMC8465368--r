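#' Construct a contact map object
#'
#' A `contact_map` holds one intrachromosomal Hi-C interaction-frequency
#' matrix together with its bin size, the (real-valued) time at which the
#' library was assayed, a chromosome label, and a per-bin mask marking bins
#' with no data. The matrix is symmetrized on construction and must be
#' square, non-negative and free of NaN (NaN entries are zeroed and the bin
#' masked).
#'
#' @param matrix square numeric matrix of interaction frequencies.
#' @param bin_size bin width in base pairs.
#' @param time real-valued time tag (e.g. day of the process).
#' @param chrom chromosome label.
#' @param symmetrize_tol asymmetries larger than this trigger a warning
#'   before the matrix is replaced by `(A + t(A))/2`.
#' @return an object of class `contact_map` with elements `matrix`,
#'   `bin_size`, `time`, `chrom` and logical `mask` (TRUE where the bin has
#'   no data).
#' @export
contact_map <- function(matrix, bin_size, time, chrom = "chr",
                        symmetrize_tol = 1e-9) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) {
    stop("contact map must be square, got ", nrow(m), " x ", ncol(m))
  }
  if (nrow(m) < 2L) stop("contact map needs at least 2 bins")
  nan_bins <- unique(c(row(m)[is.na(m)], col(m)[is.na(m)]))
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("contact map contains negative interaction frequencies")
  asym <- max(abs(m - t(m)))
  if (asym > symmetrize_tol) {
    warning("asymmetric input (max |A - t(A)| = ", signif(asym, 3),
            "); symmetrized as (A + t(A))/2")
  }
  m <- (m + t(m)) / 2
  mask <- rowSums(m) == 0
  mask[nan_bins] <- TRUE
  dimnames(m) <- NULL
  structure(
    list(matrix = m, bin_size = as.integer(bin_size), time = as.numeric(time),
         chrom = chrom, mask = mask),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s, %d bins @ %s bp, time %g, %d masked bin(s)\n",
              x$chrom, n_bins(x), format(x$bin_size, big.mark = ","),
              x$time, sum(x$mask)))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

#' Number of bins of a contact map, series or structure
#' @param x a `contact_map`, `hic_series` or `structure_4d`.
#' @return integer bin count.
#' @export
n_bins <- function(x) UseMethod("n_bins")

#' @export
n_bins.contact_map <- function(x) nrow(x$matrix)

#' @export
n_bins.hic_series <- function(x) nrow(x$maps[[1]]$matrix)

#' @export
n_bins.structure_4d <- function(x) dim(x$coords)[2]

#' Read a Hi-C contact map from a text file
#'
#' Two plain-text layouts are supported. `dense`: whitespace-delimited, n
#' rows of n numbers. `triple`: three whitespace-delimited columns
#' `bin_i bin_j value` with 0-based bin indices; a single triangle is
#' sufficient, both `(i,j)` and `(j,i)` are filled.
#'
#' A dense matrix that is asymmetric is symmetrized as `(A + t(A))/2` with
#' a warning. Bins whose entire row is zero are flagged in the mask.
#'
#' @param path file to read.
#' @param format `"dense"` or `"triple"`.
#' @param bin_size bin width in base pairs.
#' @param time real-valued time tag.
#' @param chrom chromosome label.
#' @param n bin count; required information for `triple` files whose
#'   largest index does not reach the last bin. Defaults to the inferred
#'   `max(index) + 1`.
#' @return a [contact_map].
#' @export
read_contact_map <- function(path, format = c("dense", "triple"),
                             bin_size, time, chrom = "chr", n = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    vals <- lapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L || lens[1] != length(vals)) {
      stop("dense file is not a square matrix: ", length(vals), " rows, ",
           paste(unique(lens), collapse = "/"), " columns")
    }
    m <- do.call(rbind, vals)
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "value"))
    if (any(tab$value < 0)) stop("negative interaction frequency in ", path)
    n_inf <- max(tab$i, tab$j) + 1L
    if (is.null(n)) n <- n_inf
    if (n_inf > n) {
      stop("triple index ", max(tab$i, tab$j), " exceeds declared n = ", n)
    }
    m <- matrix(0, n, n)
    m[cbind(tab$i + 1L, tab$j + 1L)] <- tab$value
    m[cbind(tab$j + 1L, tab$i + 1L)] <- tab$value
  }
  contact_map(m, bin_size = bin_size, time = time, chrom = chrom)
}

#' Write a contact map to a text file
#'
#' Inverse of [read_contact_map()]: a round trip reproduces the matrix
#' entrywise within 1e-9. Masked bins are written as zero rows (dense) or
#' simply omitted (triple, which stores the non-zero upper triangle
#' including the diagonal).
#'
#' @param map a [contact_map].
#' @param path output file.
#' @param format `"dense"` or `"triple"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "triple")) {
  stopifnot(inherits(map, "contact_map"))
  format <- match.arg(format)
  if (format == "dense") {
    lines <- apply(map$matrix, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = " "))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
  } else {
    idx <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0,
                 arr.ind = TRUE)
    lines <- sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                     format(map$matrix[idx], digits = 17, trim = TRUE,
                            scientific = FALSE))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
  }
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Assemble contact maps into a time series
#'
#' Orders the maps by their time tags and computes the common mask: bins
#' with no data in every map are excluded from restraint building and all
#' comparisons.
#'
#' @param maps list of [contact_map] objects sharing bin count, bin size
#'   and chromosome.
#' @return an object of class `hic_series` with elements `maps` (sorted by
#'   time), `times`, and logical `common_mask`.
#' @export
assemble_series <- function(maps) {
  stopifnot(is.list(maps), all(vapply(maps, inherits, TRUE, "contact_map")))
  if (length(maps) < 2L) stop("a series needs at least 2 time points")
  ns <- vapply(maps, n_bins, 1L)
  if (length(unique(ns)) != 1L) {
    stop("maps disagree on bin count: ", paste(unique(ns), collapse = ", "))
  }
  bs <- unique(vapply(maps, function(m) m$bin_size, 1L))
  if (length(bs) != 1L) stop("maps disagree on bin size")
  ch <- unique(vapply(maps, function(m) m$chrom, ""))
  if (length(ch) != 1L) stop("maps disagree on chromosome label")
  times <- vapply(maps, function(m) m$time, 1)
  if (anyDuplicated(times)) {
    stop("duplicate time tag: ", times[duplicated(times)][1])
  }
  ord <- order(times)
  maps <- maps[ord]
  common_mask <- Reduce(`&`, lapply(maps, function(m) m$mask))
  structure(
    list(maps = maps, times = times[ord], common_mask = common_mask,
         bin_size = bs, chrom = ch),
    class = "hic_series"
  )
}

#' @export
print.hic_series <- function(x, ...) {
  cat(sprintf("<hic_series> %s, %d bins @ %s bp, %d time points (%s), %d commonly masked\n",
              x$chrom, n_bins(x), format(x$bin_size, big.mark = ","),
              length(x$times), paste(x$times, collapse = ", "),
              sum(x$common_mask)))
  invisible(x)
}

#' Display a contact map as a heat image
#'
#' @param x a [contact_map].
#' @param log1p_scale plot `log1p(IF)` rather than raw frequencies.
#' @param ... passed to [graphics::image()].
#' @export
plot.contact_map <- function(x, log1p_scale = TRUE, ...) {
  m <- x$matrix
  if (log1p_scale) m <- log1p(m)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), m[, n:1],
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "bin", ylab = "bin",
                  main = sprintf("%s  t = %g", x$chrom, x$time), ...)
  invisible(x)
}
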