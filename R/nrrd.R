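#' Read and write NRRD volumes
#'
#' Minimal NRRD support for the package's dose grids and structure masks:
#' 3-D volumes, `ascii` or `raw` (little-endian) encodings, grid geometry in
#' `space origin` / `space directions` header fields (mm).  This covers the
#' files the package itself writes; it is not a general NRRD implementation.
#'
#' @param values numeric vector/array over the grid (column-major).
#' @param grid a [voxel_grid()].
#' @param path output file.
#' @param encoding `"ascii"` (text, portable) or `"raw"`.
#' @return `write_nrrd` returns `path` invisibly; `read_nrrd` returns a list
#'   with elements `grid` (a [voxel_grid()]) and `values`.
#' @export
write_nrrd <- function(values, grid, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  stopifnot(length(values) == n_voxels(grid))
  sp <- grid$spacing
  hdr <- c(
    "NRRD0004",
    "# apbidose dose/mask volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(grid$shape, collapse = " ")),
    paste0("space directions: (", sp[1], ",0,0) (0,", sp[2], ",0) (0,0,", sp[3], ")"),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", encoding),
    paste0("space origin: (", paste(grid$origin, collapse = ","), ")"),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.numeric(values), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  } else {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  enc <- get_field("encoding")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  origin <- parse_vec(get_field("space origin"))
  dirs <- regmatches(get_field("space directions"),
                     gregexpr("\\(([^)]*)\\)", get_field("space directions")))[[1]]
  dirm <- t(vapply(dirs, parse_vec, numeric(3)))
  spacing <- sqrt(rowSums(dirm^2))
  n <- prod(sizes)
  values <- if (identical(enc, "ascii")) {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else {
    readBin(con, what = double(), n = n, size = 8, endian = "little")
  }
  list(grid = voxel_grid(origin, spacing, sizes),
       values = array(values, dim = sizes))
}
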