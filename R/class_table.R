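#' Build a class table
#'
#' A class table maps integer class ids to human-readable names and the RGB
#' colors used in color-coded label masks. Ids must be consecutive from 0,
#' names unique, colors unique.
#'
#' @param name Character vector of class names.
#' @param r,g,b Integer vectors of color channels in 0--255.
#' @return A tibble with columns `id`, `name`, `r`, `g`, `b` and class
#'   `"class_table"`.
#' @export
#' @examples
#' class_table(c("background", "tissue"), r = c(0, 255), g = c(0, 0), b = c(0, 0))
class_table <- function(name, r, g, b) {
  stopifnot(length(name) >= 1, length(r) == length(name),
            length(g) == length(name), length(b) == length(name))
  tb <- tibble::tibble(
    id = seq_along(name) - 1L,
    name = as.character(name),
    r = as.integer(r), g = as.integer(g), b = as.integer(b)
  )
  validate_class_table(tb)
}

validate_class_table <- function(tb) {
  stopifnot(all(c("id", "name", "r", "g", "b") %in% names(tb)))
  if (!identical(as.integer(tb$id), seq_len(nrow(tb)) - 1L)) {
    rlang::abort("class ids must be consecutive integers starting at 0")
  }
  if (anyDuplicated(tb$name)) rlang::abort("class names must be unique")
  key <- paste(tb$r, tb$g, tb$b)
  if (anyDuplicated(key)) rlang::abort("class colors must be unique")
  if (any(tb$r < 0 | tb$r > 255 | tb$g < 0 | tb$g > 255 | tb$b < 0 | tb$b > 255)) {
    rlang::abort("color channels must lie in 0..255")
  }
  class(tb) <- c("class_table", class(tb))
  tb
}

#' The bundled 13-class cholecystectomy class table
#'
#' Thirteen classes commonly annotated in laparoscopic cholecystectomy
#' scenes: anatomy (liver, gallbladder, fat, abdominal wall, ...), the two
#' instruments (grasper, L-hook electrocautery) and small structures (blood,
#' cystic duct, hepatic vein, liver ligament). The colors are this package's
#' own palette, chosen to be mutually distinct; they are not claimed to match
#' any published dataset's color masks byte-for-byte.
#'
#' @return A 13-row [class_table()].
#' @export
cholecseg8k_classes <- function() {
  class_table(
    name = c("Black Background", "Abdominal Wall", "Liver",
             "Gastrointestinal Tract", "Fat", "Grasper",
             "Connective Tissue", "Blood", "Cystic Duct",
             "L-hook Electrocautery", "Gallbladder", "Hepatic Vein",
             "Liver Ligament"),
    r = c(0, 210, 170, 235, 255, 170, 255, 200, 240, 60, 60, 30, 120),
    g = c(0, 160, 60, 180, 220, 170, 140, 20, 240, 60, 180, 60, 90),
    b = c(0, 140, 40, 150, 120, 180, 180, 30, 60, 70, 75, 160, 200)
  )
}

#' Read / write a class table
#'
#' CSV tables have columns `id,name,r,g,b`; JSON is an array of objects with
#' the same fields. The format is chosen from the file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return `read_class_table()` returns a [class_table()];
#'   `write_class_table()` returns `path` invisibly.
#' @export
read_class_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tb <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  tb$id <- as.integer(tb$id)
  tb <- tb[order(tb$id), c("id", "name", "r", "g", "b")]
  validate_class_table(tb)
}

#' @rdname read_class_table
#' @param table A [class_table()].
#' @export
write_class_table <- function(table, path) {
  df <- as.data.frame(table)[, c("id", "name", "r", "g", "b")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

n_classes <- function(table) nrow(table)
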