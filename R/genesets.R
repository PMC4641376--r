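#' Gene set collection
#'
#' A named list of character vectors (pathway name -> member symbols) with
#' an optional description per set.  Names must be unique and every set
#' non-empty; member symbols are deduplicated and, by default, uppercased
#' so that membership is case-insensitive.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @param uppercase uppercase member symbols (default `TRUE`).
#' @return An object of class `GeneSetCollection`.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, uppercase = TRUE) {
  if (!is.list(sets)) stop("'sets' must be a list")
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (uppercase) g <- toupper(g)
    unique(g)
  })
  if (any(lengths(sets) == 0) )
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (!is.null(descriptions)) {
    if (length(descriptions) != length(sets))
      stop("'descriptions' must parallel 'sets'")
    names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets; sizes",
      if (length(x)) paste0("[", min(lengths(x)), ", ", max(lengths(x)), "]")
      else "-", "\n")
  invisible(x)
}

#' @export
`[.GeneSetCollection` <- function(x, i) {
  GeneSetCollection(unclass(x)[i],
                    descriptions = attr(x, "descriptions")[i],
                    uppercase = FALSE)
}

#' Read a GMT gene set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a line are deduplicated.
#'
#' @param path file path.
#' @param uppercase uppercase member symbols (default `TRUE`).
#' @return A [GeneSetCollection].
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection(structure(list(), names = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  GeneSetCollection(sets, descriptions = desc, uppercase = uppercase)
}

#' Write a gene set collection as GMT
#' @param collection a [GeneSetCollection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
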