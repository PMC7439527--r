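# Minimal Turtle reader/writer for the subset of Turtle this package emits:
# @prefix directives, CURIE/IRIREF resource terms, string literals with an
# optional ^^ datatype, predicate-object lists (';' / ','), anonymous bnode
# property lists '[ ... ]' and RDF collections '( ... )'.  Collections are
# expanded to rdf:first / rdf:rest / rdf:nil triples on parse.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
OHD_NS  <- "http://purl.example.org/ohd-mini/"
EX_NS   <- "http://purl.example.org/ohd-mini/practice/"

ohd_prefixes <- function() {
  c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS,
    ohd = OHD_NS, ex = EX_NS)
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

#' @noRd
ttl_tokenize <- function(text) {
  rx <- paste0(
    "@prefix",
    "|<[^<>\"{}|^`\\\\\\s]*>",                 # IRIREF
    "|\"(?:[^\"\\\\]|\\\\.)*\"",               # STRING
    "|\\^\\^",
    "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_-]*", # PNAME (no dots in local part)
    "|\\ba\\b",
    "|[][();,.]"
  )
  # strip comment lines (emitter writes '#' only at line starts)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  text <- paste(lines, collapse = "\n")
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  # verify everything except whitespace was consumed
  leftover <- text
  regmatches(leftover, list(m)) <- list(rep("", length(toks)))
  if (grepl("[^\\s]", leftover, perl = TRUE)) {
    bad <- regmatches(leftover, regexpr("[^\\s]+", leftover, perl = TRUE))
    stop("Turtle tokenizer: unexpected input near '", bad, "'")
  }
  toks
}

# Recursive-descent parser.  Returns list(prefixes = named chr,
# triples = tibble(subject, predicate, object, obj_kind, datatype)).
#' @noRd
ttl_parse <- function(text) {
  toks <- ttl_tokenize(text)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$toks <- toks
  env$prefixes <- character(0)
  env$n_bnode <- 0L
  env$subj <- character(0)
  env$pred <- character(0)
  env$obj <- character(0)
  env$kind <- character(0)
  env$dtype <- character(0)

  peek <- function() if (env$i <= length(env$toks)) env$toks[[env$i]] else NA_character_
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  expect <- function(tok) {
    t <- advance()
    if (!identical(t, tok)) stop("Turtle parse error: expected '", tok, "' got '", t, "'")
    t
  }
  emit <- function(s, p, o, kind, dt = NA_character_) {
    n <- length(env$subj) + 1L
    env$subj[n] <- s; env$pred[n] <- p; env$obj[n] <- o
    env$kind[n] <- kind; env$dtype[n] <- dt
  }
  new_bnode <- function() {
    env$n_bnode <- env$n_bnode + 1L
    paste0("_:b", env$n_bnode)
  }
  expand <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    if (identical(tok, "a")) return(paste0(RDF_NS, "type"))
    pos <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, pos - 1L)
    loc <- substr(tok, pos + 1L, nchar(tok))
    ns <- env$prefixes[[pfx]]
    if (is.null(ns) || is.na(ns)) stop("Turtle parse error: undeclared prefix '", pfx, ":'")
    paste0(ns, loc)
  }
  is_resource_tok <- function(tok) {
    !is.na(tok) && (startsWith(tok, "<") ||
      grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_-]*$", tok) || identical(tok, "a"))
  }

  parse_object <- function() {
    tok <- peek()
    if (identical(tok, "[")) {
      advance()
      b <- new_bnode()
      if (!identical(peek(), "]")) parse_pol(b)
      expect("]")
      list(value = b, kind = "blank", dtype = NA_character_)
    } else if (identical(tok, "(")) {
      advance()
      items <- list()
      while (!identical(peek(), ")")) items[[length(items) + 1L]] <- parse_object()
      expect(")")
      if (length(items) == 0L) {
        list(value = paste0(RDF_NS, "nil"), kind = "iri", dtype = NA_character_)
      } else {
        nodes <- vapply(seq_along(items), function(k) new_bnode(), "")
        for (k in seq_along(items)) {
          emit(nodes[k], paste0(RDF_NS, "first"),
               items[[k]]$value, items[[k]]$kind, items[[k]]$dtype)
          nxt <- if (k < length(items)) nodes[k + 1L] else paste0(RDF_NS, "nil")
          nxt_kind <- if (k < length(items)) "blank" else "iri"
          emit(nodes[k], paste0(RDF_NS, "rest"), nxt, nxt_kind)
        }
        list(value = nodes[1L], kind = "blank", dtype = NA_character_)
      }
    } else if (!is.na(tok) && startsWith(tok, "\"")) {
      advance()
      val <- ttl_unescape(substr(tok, 2L, nchar(tok) - 1L))
      dt <- NA_character_
      if (identical(peek(), "^^")) {
        advance()
        dt <- expand(advance())
      }
      list(value = val, kind = "literal", dtype = dt)
    } else if (is_resource_tok(tok)) {
      advance()
      list(value = expand(tok), kind = "iri", dtype = NA_character_)
    } else {
      stop("Turtle parse error: unexpected token '", tok, "'")
    }
  }

  parse_pol <- function(subject) {
    repeat {
      p <- expand(advance())
      repeat {
        o <- parse_object()
        emit(subject, p, o$value, o$kind, o$dtype)
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else break
    }
  }

  while (!is.na(peek())) {
    tok <- peek()
    if (identical(tok, "@prefix")) {
      advance()
      pn <- advance()                       # e.g. "ohd:"
      pfx <- sub(":$", "", pn)
      iri <- advance()
      env$prefixes[[pfx]] <- substr(iri, 2L, nchar(iri) - 1L)
      expect(".")
    } else if (identical(tok, "[")) {
      advance()
      b <- new_bnode()
      if (!identical(peek(), "]")) parse_pol(b)
      expect("]")
      if (!identical(peek(), ".")) parse_pol(b)
      expect(".")
    } else {
      s <- expand(advance())
      parse_pol(s)
      expect(".")
    }
  }

  list(
    prefixes = env$prefixes,
    triples = tibble::tibble(
      subject = env$subj, predicate = env$pred, object = env$obj,
      obj_kind = env$kind, datatype = env$dtype
    )
  )
}

# Compact a full IRI back to a CURIE where a known prefix matches.
#' @noRd
iri_to_curie <- function(iri, prefixes = ohd_prefixes()) {
  out <- iri
  ord <- order(nchar(prefixes), decreasing = TRUE)
  for (k in ord) {
    ns <- prefixes[[k]]
    # only rewrite not-yet-rewritten entries; NAs pass through
    hit <- !is.na(iri) & startsWith(iri, ns) & out == iri
    out[hit] <- paste0(names(prefixes)[k], ":", substr(iri[hit], nchar(ns) + 1L, nchar(iri[hit])))
  }
  out
}

#' @noRd
curie_to_iri <- function(curie, prefixes = ohd_prefixes()) {
  pos <- regexpr(":", curie, fixed = TRUE)
  pfx <- substr(curie, 1L, pos - 1L)
  loc <- substr(curie, pos + 1L, nchar(curie))
  ns <- unname(prefixes[pfx])
  ifelse(is.na(ns), curie, paste0(ns, loc))
}

#' @noRd
ttl_prefix_block <- function(prefixes = ohd_prefixes()) {
  paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .", collapse = "\n")
}

# Render one term for the writer: CURIEs pass through, literals get quoted.
#' @noRd
ttl_term <- function(value, kind, datatype = NA_character_) {
  ifelse(kind == "literal",
         paste0("\"", ttl_escape(value), "\"",
                ifelse(is.na(datatype), "",
                       paste0("^^", iri_to_curie(datatype)))),
         value)
}
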