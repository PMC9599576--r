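# Minimal JCAMP-DX reader for vibrational spectra. Supports single- and
# multi-block files with ##XYDATA=(X++(Y..Y)) tables (AFFN numerals,
# FIRSTX/LASTX/NPOINTS/XFACTOR/YFACTOR) and explicit (XY..XY) pair tables
# under ##XYDATA or ##XYPOINTS. Compression schemes (SQZ/DIF/DUP) and data
# classes other than plain spectra are out of scope.

#' Read spectra from a JCAMP-DX file
#'
#' Parses every block of a (possibly compound) JCAMP-DX file into one
#' spectrum each. When the blocks share an identical abscissa the result is
#' returned as-is; otherwise all blocks are linearly interpolated onto a
#' common grid spanning the overlap of their ranges, with as many points as
#' the densest block carries over that overlap.
#'
#' @param path JCAMP-DX file path.
#' @return a [spectrum_set()] with one row per block.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)           # strip comments
  blocks <- .jcamp_split_blocks(lines)
  if (length(blocks) == 0L)
    stop("no JCAMP-DX block found in ", path, call. = FALSE)
  xy <- lapply(blocks, .jcamp_parse_block)
  grids <- lapply(xy, `[[`, "x")
  same <- all(vapply(grids, function(g)
    length(g) == length(grids[[1L]]) &&
      all(abs(g - grids[[1L]]) < 1e-9), logical(1L)))
  if (same) {
    intens <- do.call(rbind, lapply(xy, `[[`, "y"))
    return(spectrum_set(wavenumber_grid(grids[[1L]]), intens))
  }
  lo <- max(vapply(grids, min, numeric(1L)))
  hi <- min(vapply(grids, max, numeric(1L)))
  if (!(lo < hi))
    stop("JCAMP blocks have no overlapping wavenumber range", call. = FALSE)
  dens <- max(vapply(grids, function(g) sum(g >= lo & g <= hi), numeric(1L)))
  common <- wavenumber_grid(seq(lo, hi, length.out = max(2L, dens)))
  intens <- do.call(rbind, lapply(xy, function(b)
    stats::approx(b$x, b$y, xout = as.numeric(common))$y))
  spectrum_set(common, intens)
}

.jcamp_split_blocks <- function(lines) {
  starts <- grep("^\\s*##TITLE=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) return(list())
  ends <- grep("^\\s*##END=", lines, ignore.case = TRUE)
  blocks <- list()
  for (s in starts) {
    e <- ends[ends > s]
    e <- if (length(e)) min(e) else length(lines)
    chunk <- lines[s:e]
    # skip pure link blocks (compound-file wrappers without data)
    if (any(grepl("^\\s*##(XYDATA|XYPOINTS)=", chunk, ignore.case = TRUE)))
      blocks[[length(blocks) + 1L]] <- chunk
  }
  blocks
}

.jcamp_field <- function(lines, key, default = NA_real_) {
  pat <- paste0("^\\s*##", key, "=\\s*(.*)$")
  hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
  if (length(hit) == 0L) return(default)
  as.numeric(sub(pat, "\\1", hit[1L], ignore.case = TRUE))
}

.jcamp_parse_block <- function(lines) {
  idx <- grep("^\\s*##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (length(idx) == 0L)
    stop("JCAMP block has no XYDATA", call. = FALSE)
  idx <- idx[1L]
  form <- toupper(sub("^\\s*##(XYDATA|XYPOINTS)=\\s*", "", lines[idx],
                      ignore.case = TRUE))
  stop_at <- grep("^\\s*##", lines[-seq_len(idx)])
  body <- if (length(stop_at)) lines[idx + seq_len(min(stop_at) - 1L)]
          else lines[-seq_len(idx)]
  body <- body[nzchar(trimws(body))]
  if (grepl("X\\+\\+", form)) {
    xf <- .jcamp_field(lines, "XFACTOR", 1)
    yf <- .jcamp_field(lines, "YFACTOR", 1)
    firstx <- .jcamp_field(lines, "FIRSTX")
    lastx <- .jcamp_field(lines, "LASTX")
    np <- .jcamp_field(lines, "NPOINTS")
    if (anyNA(c(firstx, lastx, np)))
      stop("JCAMP (X++(Y..Y)) block lacks FIRSTX/LASTX/NPOINTS",
           call. = FALSE)
    toks <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), as.numeric)
    y <- unlist(lapply(toks, function(t) t[-1L])) * yf
    if (length(y) != np)
      stop("JCAMP block declares ", np, " points but carries ", length(y),
           call. = FALSE)
    x <- seq(firstx * xf, lastx * xf, length.out = np)
  } else {
    toks <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (length(toks) %% 2L != 0L)
      stop("odd token count in JCAMP (XY..XY) table", call. = FALSE)
    x <- toks[seq(1L, length(toks), by = 2L)]
    y <- toks[seq(2L, length(toks), by = 2L)]
  }
  if (anyNA(x) || anyNA(y))
    stop("unparseable numeral in JCAMP data table", call. = FALSE)
  o <- order(x)
  list(x = x[o], y = y[o])
}
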