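#' Inverse hyperbolic sine transform
#'
#' Variance-stabilizing transform applied to binned signal values:
#' `asinh(x) = ln(x + sqrt(x^2 + 1))`. It behaves like `log` for large
#' signal but is defined at zero (and for negatives), which suits
#' -log10 p coverage tracks. All model fitting and all quality measures
#' operate on this transformed scale; the transform is never reversed
#' for evaluation.
#'
#' @param x numeric vector of finite signal values.
#' @return the transformed values, same length as `x`.
#' @examples
#' asinh_transform(0)      # 0
#' asinh_transform(1)      # log(1 + sqrt(2)) = 0.881374
#' @export
asinh_transform <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  stopifnot_finite(x, "signal values")
  asinh(x)
}

#' Build a fixed-width genomic bin index
#'
#' Tiles the given chromosome lengths into constant-width bins
#' (0-based, half-open coordinates; the last partial bin is dropped so
#' every bin has the same width). The bin index defines the genome axis
#' of the tensor: its length is `I` and bin `i` is row `i` of every
#' signal vector.
#'
#' @param seqlengths named integer vector of chromosome lengths (bp).
#' @param width bin width in bp (default 25).
#' @return a `GRanges` of bins with constant width, sorted.
#' @export
genomic_bins <- function(seqlengths, width = 25L) {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("seqlengths must be named by chromosome")
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  grl <- lapply(names(seqlengths), function(ch) {
    n <- seqlengths[[ch]] %/% width
    if (n < 1L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = seq_len(n) * width - width + 1L, width = width))
  })
  bins <- suppressWarnings(do.call(c, grl))
  S4Vectors::metadata(bins)$bin_width <- width
  bins
}

#' Read / write a 4-column bedGraph track
#'
#' Thin wrappers around `rtracklayer::import()` / `export()` for
#' bedGraph (chrom, start, end, value; tab-separated, track lines
#' ignored). Intervals are validated to be sorted, non-overlapping,
#' with finite values.
#'
#' @param path file path.
#' @return `read_bedgraph`: a `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  validate_track(gr)
  gr
}

#' @rdname read_bedgraph
#' @param track a `GRanges` with a numeric `score` column.
#' @export
write_bedgraph <- function(track, path) {
  validate_track(track)
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

validate_track <- function(track) {
  if (!methods::is(track, "GRanges") || is.null(track$score))
    stop("track must be a GRanges with a score column")
  stopifnot_finite(track$score, "track values")
  if (any(GenomicRanges::width(track) < 1L)) stop("track intervals must have end > start")
  srt <- GenomicRanges::sort(track)
  if (!identical(GenomicRanges::start(srt), GenomicRanges::start(track)) &&
      !all(srt == track))
    stop("track intervals must be sorted")
  if (!IRanges::isDisjoint(track)) stop("track intervals must be non-overlapping")
  invisible(track)
}

#' Average a signal track into fixed-width bins
#'
#' Each bin value is the base-pair-weighted mean of the interval values
#' overlapping the bin; bases covered by no interval contribute value 0.
#' Bins on chromosomes absent from the track get value 0 with a
#' warning. This conserves signal mass: `sum(value * width)` over bins
#' equals the same sum over the track wherever the bins tile the
#' covered region.
#'
#' @param track a `GRanges` with a `score` column (see [read_bedgraph()]).
#' @param bins a bin index from [genomic_bins()].
#' @return numeric vector of per-bin means, length `length(bins)`.
#' @export
bin_track <- function(track, bins) {
  validate_track(track)
  if (length(bins) == 0L) return(numeric(0))
  missing_chrom <- setdiff(
    as.character(unique(GenomeInfoDb::seqnames(bins))),
    as.character(unique(GenomeInfoDb::seqnames(track))))
  if (length(missing_chrom))
    warning("bins on chromosome(s) absent from track, filled with 0: ",
            paste(missing_chrom, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(bins, track, ignore.strand = TRUE)
  out <- numeric(length(bins))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(IRanges::ranges(bins)[qi], IRanges::ranges(track)[si])
    contrib <- IRanges::width(ov) * track$score[si]
    sums <- tapply(contrib, qi, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out / GenomicRanges::width(bins)
}

#' Observed signal tensor
#'
#' Container for the J x K x I tensor of signal values. Missingness is
#' always fiber-wise: an experiment (cell type j, assay k) is either
#' fully observed along the genome axis or fully absent. Internally the
#' values are stored as a dense array with `NA` fibers plus a J x K
#' logical availability mask.
#'
#' @param values named list mapping `"<cell_type>|<assay>"` to length-I
#'   numeric vectors, or a J x K x I array with NA for missing fibers.
#' @param cell_types,assays character label vectors (lengths J, K).
#' @param bins the genome bin index (a `GRanges` from [genomic_bins()],
#'   or an integer I for label-free synthetic coordinates).
#' @param transform `"raw"` or `"asinh"`.
#' @return an object of class `obs_tensor` with elements `values`
#'   (J x K x I array), `mask` (J x K logical), `cell_types`, `assays`,
#'   `bins`, `transform`.
#' @export
observed_tensor <- function(values, cell_types, assays, bins, transform = c("raw", "asinh")) {
  transform <- match.arg(transform)
  J <- length(cell_types); K <- length(assays)
  if (J < 1L || K < 1L) stop("need at least one cell type and one assay")
  if (anyDuplicated(cell_types) || anyDuplicated(assays))
    stop("cell type and assay labels must be unique")
  I <- if (methods::is(bins, "GRanges")) length(bins) else as.integer(bins)
  if (I < 1L) stop("need at least one genomic bin")
  if (is.array(values)) {
    if (!identical(dim(values), c(J, K, I))) stop("values array must be J x K x I")
    arr <- values
  } else {
    arr <- array(NA_real_, dim = c(J, K, I))
    for (nm in names(values)) {
      parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
      j <- match(parts[1], cell_types); k <- match(parts[2], assays)
      if (is.na(j) || is.na(k)) stop("unknown experiment key: ", nm)
      v <- values[[nm]]
      if (length(v) != I) stop("experiment ", nm, " does not have length I")
      arr[j, k, ] <- v
    }
  }
  mask <- !is.na(arr[, , 1, drop = FALSE])[, , 1, drop = TRUE]
  mask <- matrix(mask, J, K)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    fib <- arr[j, k, ]
    if (mask[j, k]) {
      if (!all(is.finite(fib))) stop("observed fiber (", j, ",", k, ") has non-finite values")
    } else if (!all(is.na(fib))) stop("missingness must be fiber-wise, found partial fiber")
  }
  if (!any(mask)) stop("tensor has no observed experiments")
  structure(list(values = arr, mask = mask, cell_types = cell_types,
                 assays = assays, bins = bins, transform = transform),
            class = "obs_tensor")
}

#' @export
print.obs_tensor <- function(x, ...) {
  cat(sprintf("obs_tensor: %d cell types x %d assays x %d bins (%s scale)\n",
              length(x$cell_types), length(x$assays), tensor_I(x), x$transform))
  cat(sprintf("  %d / %d experiments observed (%.1f%% missing)\n",
              sum(x$mask), length(x$mask), 100 * (1 - mean(x$mask))))
  invisible(x)
}

tensor_I <- function(D) dim(D$values)[3]

#' Observed experiment keys of a tensor
#'
#' @param D an `obs_tensor`.
#' @return data.frame with integer columns `cell_type`, `assay` (1-based
#'   indices), one row per observed experiment, in column-major order.
#' @export
observed_keys <- function(D) {
  idx <- which(D$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(cell_type = idx[, 1], assay = idx[, 2])
}

#' Filter cell types and assays with too few experiments
#'
#' Iteratively removes cell types and assays with fewer than
#' `min_count` observed experiments until a fixed point is reached, so
#' that every retained cell type and assay has at least `min_count`
#' observed experiments among the retained labels. With the default
#' `min_count = 5` applied to the Roadmap Consolidated availability
#' grid this retains 127 cell types and 24 assays (1014 experiments).
#'
#' @param mask J x K logical availability matrix (rows = cell types).
#' @param min_count minimum experiments per retained cell type / assay.
#' @return list with integer index vectors `cell_types` and `assays` of
#'   retained rows and columns.
#' @export
filter_min_support <- function(mask, min_count = 5L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  keep_j <- seq_len(nrow(mask)); keep_k <- seq_len(ncol(mask))
  repeat {
    sub <- mask[keep_j, keep_k, drop = FALSE]
    bad_j <- rowSums(sub) < min_count
    bad_k <- colSums(sub) < min_count
    if (!any(bad_j) && !any(bad_k)) break
    keep_j <- keep_j[!bad_j]
    keep_k <- keep_k[!bad_k]
    if (length(keep_j) == 0L || length(keep_k) == 0L)
      stop("filtering removed every cell type or assay (empty tensor)")
  }
  list(cell_types = keep_j, assays = keep_k)
}

#' Stratified train/validation/test splits of the experiment grid
#'
#' Assigns every observed experiment to one of `n_test` disjoint test
#' sets, stratified so that for each cell type (and, where counts
#' allow, each assay) the per-test-set counts differ by at most one.
#' For each test set, the remaining (training) experiments are further
#' partitioned into `n_folds` validation folds of near-equal size.
#' Deterministic given `seed`.
#'
#' @param keys data.frame of observed keys (see [observed_keys()]).
#' @param n_test number of test sets (default 5).
#' @param n_folds validation folds per test set (default 8).
#' @param seed integer seed.
#' @return an object of class `split_assignment`: list with `keys`,
#'   integer vector `test_set` (per key, 1..n_test), and integer matrix
#'   `folds` (keys x n_test; `folds[m, s]` is the validation fold of key
#'   m within split s, `NA` when key m is in test set s).
#' @export
make_splits <- function(keys, n_test = 5L, n_folds = 8L, seed = 1L) {
  n_test <- as.integer(n_test); n_folds <- as.integer(n_folds)
  if (n_test < 2L) stop("n_test must be >= 2")
  if (n_folds < 1L) stop("n_folds must be >= 1")
  M <- nrow(keys)
  if (M < n_test) stop("fewer observed experiments than test sets")
  test_set <- integer(M)
  with_seed(derive_seed(seed, 1L), {
    assay_count <- matrix(0L, max(keys$assay), n_test)
    total_count <- integer(n_test)
    for (j in unique(keys$cell_type[order(runif(M))])) {
      rows <- which(keys$cell_type == j)
      rows <- rows[order(runif(length(rows)))]
      ct_count <- integer(n_test)
      for (m in rows) {
        # eligible sets keep per-cell-type counts within 1; among those,
        # greedily balance by assay, then by overall size
        elig <- which(ct_count == min(ct_count))
        a <- keys$assay[m]
        elig <- elig[order(assay_count[a, elig], total_count[elig], elig)]
        s <- elig[1]
        test_set[m] <- s
        ct_count[s] <- ct_count[s] + 1L
        assay_count[a, s] <- assay_count[a, s] + 1L
        total_count[s] <- total_count[s] + 1L
      }
    }
  })
  folds <- matrix(NA_integer_, M, n_test)
  for (s in seq_len(n_test)) {
    train_rows <- which(test_set != s)
    with_seed(derive_seed(seed, 2L, s), {
      perm <- train_rows[order(runif(length(train_rows)))]
    })
    folds[perm, s] <- rep_len(seq_len(n_folds), length(perm))
  }
  structure(list(keys = keys, test_set = test_set, folds = folds,
                 n_test = n_test, n_folds = n_folds, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d experiments, %d test sets x %d folds (seed %d)\n",
              nrow(x$keys), x$n_test, x$n_folds, x$seed))
  print(table(test_set = x$test_set))
  invisible(x)
}

#' Write / read the plain-text tensor container
#'
#' A tensor container is a directory holding: `cell_types.txt` and
#' `assays.txt` (one label per line), `bins.bed` (3-column BED-like bin
#' index), `manifest.tsv` (cell_type, assay, file), `transform.txt`,
#' and one whitespace-free numeric file per observed experiment under
#' `data/`.
#'
#' @param D an `obs_tensor`.
#' @param dir directory to create/read.
#' @return `write_tensor_container` returns `dir` invisibly;
#'   `read_tensor_container` returns an `obs_tensor`.
#' @export
write_tensor_container <- function(D, dir) {
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  writeLines(D$cell_types, file.path(dir, "cell_types.txt"))
  writeLines(D$assays, file.path(dir, "assays.txt"))
  writeLines(D$transform, file.path(dir, "transform.txt"))
  if (methods::is(D$bins, "GRanges")) {
    bed <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(D$bins)),
                      start = GenomicRanges::start(D$bins) - 1L,
                      end = GenomicRanges::end(D$bins))
  } else {
    w <- 25L
    bed <- data.frame(chrom = "chrS", start = (seq_len(tensor_I(D)) - 1L) * w,
                      end = seq_len(tensor_I(D)) * w)
  }
  write.table(bed, file.path(dir, "bins.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  keys <- observed_keys(D)
  files <- sprintf("data/exp_%03d_%03d.txt", keys$cell_type, keys$assay)
  manifest <- data.frame(cell_type = D$cell_types[keys$cell_type],
                         assay = D$assays[keys$assay], file = files)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (m in seq_len(nrow(keys)))
    writeLines(format(D$values[keys$cell_type[m], keys$assay[m], ], digits = 17),
               file.path(dir, files[m]))
  invisible(dir)
}

#' @rdname write_tensor_container
#' @export
read_tensor_container <- function(dir) {
  cell_types <- readLines(file.path(dir, "cell_types.txt"))
  assays <- readLines(file.path(dir, "assays.txt"))
  transform <- readLines(file.path(dir, "transform.txt"))[1]
  bed <- read.table(file.path(dir, "bins.bed"), sep = "\t",
                    col.names = c("chrom", "start", "end"))
  bins <- GenomicRanges::GRanges(bed$chrom,
                                 IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  manifest <- read.table(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE)
  vals <- list()
  for (m in seq_len(nrow(manifest))) {
    key <- paste(manifest$cell_type[m], manifest$assay[m], sep = "|")
    vals[[key]] <- as.numeric(readLines(file.path(dir, manifest$file[m])))
  }
  observed_tensor(vals, cell_types, assays, bins, transform)
}
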