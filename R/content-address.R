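#' @title Content addressing
#' @description
#' Every model object and relation gets a deterministic unique ID derived
#' from its content: the object is serialized into a canonical byte string
#' (type tag plus fields with keys sorted lexicographically, UTF-8, no
#' insignificant whitespace) and hashed with SHA-256, hex-encoded. Equal
#' content therefore always yields equal IDs, across runs and platforms,
#' which is what makes duplicate records from different imports collapse
#' onto one node.
#'
#' Canonical serialization format (bit-exact, so independent
#' implementations agree on IDs):
#' \itemize{
#'   \item a record is `<kind>{<key>:<value>,...}` with keys in
#'     lexicographic (C-locale) order and no whitespace;
#'   \item strings are double-quoted with JSON escaping of `\"`, `\\` and
#'     control characters;
#'   \item booleans are `true`/`false`;
#'   \item numbers use the shortest decimal form that round-trips to the
#'     same double (so 0.9 and 0.90 serialize — and hash — identically);
#'   \item nested maps (`payload`, `props`) use the same `{k:v,...}` form.
#' }
#' @name content-address
NULL

# shortest decimal round-trip representation of a double
canonical_number <- function(x) {
  x <- as.numeric(x)
  if (!is.finite(x)) stop_validation("non-finite number cannot be serialized")
  if (x == floor(x) && abs(x) < 2^53) return(sprintf("%.0f", x))
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

canonical_string <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  # control characters to \u00XX escapes
  if (grepl("[\x01-\x1f]", s)) {
    for (code in 1:31) {
      ch <- rawToChar(as.raw(code))
      if (grepl(ch, s, fixed = TRUE))
        s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE)
    }
  }
  paste0("\"", s, "\"")
}

canonical_scalar <- function(v) {
  if (is.character(v)) canonical_string(v)
  else if (is.logical(v)) if (v) "true" else "false"
  else canonical_number(v)
}

canonical_map <- function(m) {
  if (length(m) == 0L) return("{}")
  keys <- sort(names(m), method = "radix")
  parts <- vapply(keys, function(k)
    paste0(k, ":", canonical_scalar(m[[k]])), character(1))
  paste0("{", paste(parts, collapse = ","), "}")
}

#' Canonical serialization of a model object
#'
#' @param object A `bg_entity`, `bg_identifier`, `bg_data` or
#'   `bg_relation`.
#' @return The canonical byte string (UTF-8 character scalar) the object's
#'   ID is hashed from. The kind tag participates, so objects of different
#'   kinds never serialize identically even with equal field values.
#' @export
bg_serialize <- function(object) {
  kind <- bg_kind(object)
  fields <- switch(kind,
    entity = sprintf("entity_type:%s,primary_identifier:%s",
                     canonical_string(object$entity_type),
                     canonical_string(object$primary_identifier)),
    identifier = sprintf("id_type:%s,title:%s,value:%s",
                         canonical_string(object$id_type),
                         canonical_string(object$title),
                         canonical_string(object$value)),
    data = sprintf("payload:%s,source_label:%s",
                   canonical_map(object$payload),
                   canonical_string(object$source_label)),
    relation = sprintf("label:%s,props:%s,source_id:%s,target_id:%s",
                       canonical_string(object$label),
                       canonical_map(object$props),
                       canonical_string(object$source_id),
                       canonical_string(object$target_id))
  )
  paste0(kind, "{", fields, "}")
}

#' Content-address a model object
#'
#' Computes the object's unique ID: SHA-256 of its canonical
#' serialization, as a 64-character lowercase hexadecimal string.
#' Deterministic — repeated calls on equal content return equal IDs — and
#' independent of payload/props key order.
#'
#' @inheritParams bg_serialize
#' @return 64-character lowercase hex string.
#' @examples
#' bg_id(bg_entity("gene", "CDKN1A"))
#' @export
bg_id <- function(object) {
  digest::digest(enc2utf8(bg_serialize(object)),
                 algo = "sha256", serialize = FALSE)
}
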