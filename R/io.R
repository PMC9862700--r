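# Reading and writing product databases (CSV and JSON).
#
# CSV layout: one row per product; scalar columns as in product_record();
# list-valued fields are packed into single cells -- claims/indicators as
# ";"-separated tokens, ingredients as ";"-separated "name|class|form|pct"
# entries (empty pct = undeclared). Comma separator, UTF-8, dot decimal,
# empty cell = absent. JSON: an array of objects with a nested ingredient
# array. Both formats round-trip bit-exactly through read_products().

pack_tokens <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

unpack_tokens <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) || v == "") character() else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

pack_ingredients <- function(ings) {
  vapply(ings, function(ing) {
    if (nrow(ing) == 0) return("")
    pct <- ifelse(is.na(ing$declared_pct), "",
      sprintf("%.17g", ing$declared_pct) # shortest-safe, round-trips doubles
    )
    paste(
      paste(ing$name, ing$eligibility_class, ing$form, pct, sep = "|"),
      collapse = ";"
    )
  }, character(1))
}

unpack_ingredients <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) || v == "") return(empty_ingredients())
    parts <- strsplit(strsplit(v, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
    tibble::tibble(
      name = vapply(parts, `[`, character(1), 1),
      eligibility_class = vapply(parts, `[`, character(1), 2),
      form = vapply(parts, `[`, character(1), 3),
      declared_pct = vapply(parts, function(p) {
        if (length(p) < 4 || p[4] == "") NA_real_ else as.numeric(p[4])
      }, numeric(1))
    )
  })
}

scalar_cols <- function() {
  c("product_id", "name", "category", "origin", "matrix", "basis",
    nutrient_fields)
}

#' Write a product database
#'
#' @param products A validated product tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_products()]
#' @export
write_products <- function(products, path, format = c("csv", "json")) {
  format <- match.arg(format)
  flat <- products[scalar_cols()]
  flat$ingredients <- pack_ingredients(products$ingredients)
  flat$claims <- pack_tokens(products$claims)
  flat$indicators <- pack_tokens(products$indicators)
  if (format == "csv") {
    readr::write_csv(flat, path, na = "")
  } else {
    recs <- lapply(seq_len(nrow(products)), function(i) {
      rec <- as.list(products[i, scalar_cols()])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      ing <- products$ingredients[[i]]
      rec$ingredients <- lapply(seq_len(nrow(ing)), function(j) {
        e <- as.list(ing[j, ])
        if (is.na(e$declared_pct)) e$declared_pct <- NULL
        e
      })
      rec$claims <- as.list(products$claims[[i]])
      rec$indicators <- as.list(products$indicators[[i]])
      rec
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a product database
#'
#' Reads a CSV or JSON product file, validates every record, and separates
#' malformed rows into a rejects report rather than dropping them silently.
#' Unknown columns are ignored; empty numeric cells parse as absent (`NA`).
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A list with `products` (validated tibble) and `rejects` (tibble
#'   with `row`, `product_id`, `reason`).
#' @export
read_products <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(
        .default = readr::col_character(),
        energy_kcal = readr::col_double(), protein_g = readr::col_double(),
        fat_g = readr::col_double(), sfa_g = readr::col_double(),
        carb_g = readr::col_double(), sugars_g = readr::col_double(),
        fiber_g = readr::col_double(), salt_g = readr::col_double()
      ),
      na = "", progress = FALSE
    )
    missing_cols <- setdiff(scalar_cols(), names(raw))
    if (length(missing_cols) > 0) {
      stop("missing columns: ", paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    products <- raw[scalar_cols()]
    products$ingredients <- unpack_ingredients(
      if ("ingredients" %in% names(raw)) raw$ingredients else rep(NA_character_, nrow(raw))
    )
    products$claims <- unpack_tokens(
      if ("claims" %in% names(raw)) raw$claims else rep(NA_character_, nrow(raw))
    )
    products$indicators <- unpack_tokens(
      if ("indicators" %in% names(raw)) raw$indicators else rep(NA_character_, nrow(raw))
    )
  } else {
    recs <- jsonlite::read_json(path)
    products <- dplyr::bind_rows(lapply(recs, json_to_row))
    if (length(recs) == 0) {
      products <- product_record("x", "x", "milk", "plant", "grain")[0, ]
    }
  }
  v <- validate_products(tibble::as_tibble(products))
  list(products = v$valid, rejects = v$rejects)
}

json_to_row <- function(rec) {
  num <- function(field) {
    if (is.null(rec[[field]])) NA_real_ else as.numeric(rec[[field]])
  }
  chr <- function(field, default = NA_character_) {
    if (is.null(rec[[field]])) default else as.character(rec[[field]])
  }
  ing <- if (length(rec$ingredients) == 0) {
    empty_ingredients()
  } else {
    dplyr::bind_rows(lapply(rec$ingredients, function(e) {
      tibble::tibble(
        name = as.character(e$name),
        eligibility_class = as.character(e$eligibility_class),
        form = as.character(e$form),
        declared_pct = if (is.null(e$declared_pct)) NA_real_ else as.numeric(e$declared_pct)
      )
    }))
  }
  tibble::tibble(
    product_id = chr("product_id"), name = chr("name"),
    category = chr("category"), origin = chr("origin"),
    matrix = chr("matrix"), basis = chr("basis", "per_100g"),
    energy_kcal = num("energy_kcal"), protein_g = num("protein_g"),
    fat_g = num("fat_g"), sfa_g = num("sfa_g"), carb_g = num("carb_g"),
    sugars_g = num("sugars_g"), fiber_g = num("fiber_g"),
    salt_g = num("salt_g"),
    ingredients = list(ing),
    claims = list(unlist(rec$claims) %||% character()),
    indicators = list(unlist(rec$indicators) %||% character())
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
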