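# Text-level preprocessing of the equation DSL.
#
# Model equations are written in a Python-flavoured mathematical syntax that is
# almost R: the differences are Python-style conditionals (`if c: a else: b`),
# the word operators `and`/`or`/`not`, boolean literals `true`/`false`, and
# derivative tokens `dX/dt`.  This file rewrites statement text into a form
# R's parser accepts; all semantic analysis happens on the resulting language
# objects (see dsl-parse.R / dsl-resolve.R).

# Flag keywords that may legally appear after the trailing `:` of a statement.
dsl_flag_keywords <- c(
  "init", "min", "max", "population", "postsynaptic", "int", "bool",
  "explicit", "implicit", "exponential", "midpoint", "event-driven",
  "proba", "w", "d", "all"
)

dsl_method_flags <- c("explicit", "implicit", "exponential", "midpoint",
                      "event-driven")

# Split a multi-line block into individual statements.  Statements are
# separated by newlines or semicolons; `#` starts a comment to end of line.
dsl_split_statements <- function(text) {
  if (is.null(text) || length(text) == 0L) return(character(0))
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", lines)
  stmts <- unlist(strsplit(lines, ";", fixed = TRUE), use.names = FALSE)
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

# Per-character bracket depth ( '(' and '[' ), measured *before* each char.
dsl_depth <- function(chars) {
  depth <- integer(length(chars))
  d <- 0L
  for (i in seq_along(chars)) {
    depth[i] <- d
    if (chars[i] %in% c("(", "[")) d <- d + 1L
    else if (chars[i] %in% c(")", "]")) d <- d - 1L
  }
  depth
}

# Positions of a single character at top level (depth 0).
dsl_toplevel_pos <- function(s, char) {
  chars <- strsplit(s, "")[[1]]
  depth <- dsl_depth(chars)
  which(chars == char & depth == 0L)
}

# Split "body : flags" on the *last* top-level colon whose tail looks like a
# flag list.  The colon also appears inside conditionals (`if c: a else: b`),
# so the tail must match the flag grammar to count.
dsl_strip_flags <- function(stmt) {
  pos <- dsl_toplevel_pos(stmt, ":")
  for (p in rev(pos)) {
    tail <- trimws(substr(stmt, p + 1L, nchar(stmt)))
    flags <- dsl_try_parse_flags(tail)
    if (!is.null(flags)) {
      return(list(body = trimws(substr(stmt, 1L, p - 1L)), flags = flags))
    }
  }
  list(body = trimws(stmt), flags = list())
}

# Parse a flag list "key, key = value, ..." -> named list, or NULL if the text
# is not a valid flag list.  With `keywords = NULL` any identifier-shaped key
# is accepted (used where a trailing colon is unambiguously a flag separator).
dsl_try_parse_flags <- function(s, keywords = dsl_flag_keywords) {
  if (!nzchar(s)) return(NULL)
  chars <- strsplit(s, "")[[1]]
  depth <- dsl_depth(chars)
  cuts <- which(chars == "," & depth == 0L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  items <- trimws(substring(s, starts, ends))
  out <- list()
  for (item in items) {
    m <- regmatches(item, regexec("^([A-Za-z][A-Za-z-]*)(\\s*=\\s*(.+))?$", item))[[1]]
    if (length(m) == 0L) return(NULL)
    key <- m[2]
    if (!is.null(keywords) && !(key %in% keywords)) return(NULL)
    val <- if (nzchar(m[3])) trimws(m[4]) else TRUE
    if (key %in% names(out)) return(NULL)
    out[[key]] <- val
  }
  out
}

# Strict variant for statements whose body cannot contain a colon (parameter
# declarations): everything after the last top-level colon is a flag list.
dsl_strip_flags_strict <- function(stmt) {
  pos <- dsl_toplevel_pos(stmt, ":")
  if (length(pos) == 0L) return(list(body = trimws(stmt), flags = list()))
  p <- pos[length(pos)]
  tail <- trimws(substr(stmt, p + 1L, nchar(stmt)))
  flags <- dsl_try_parse_flags(tail, keywords = NULL)
  if (is.null(flags)) {
    stop("malformed flag list in: ", stmt, call. = FALSE)
  }
  list(body = trimws(substr(stmt, 1L, p - 1L)), flags = flags)
}

# Locate the top-level assignment operator of a statement body.
# Returns list(lhs, op, rhs) with op in =, +=, -=, *=, /=, or NULL.
dsl_split_assign <- function(body) {
  chars <- strsplit(body, "")[[1]]
  depth <- dsl_depth(chars)
  for (i in seq_along(chars)) {
    if (chars[i] != "=" || depth[i] != 0L) next
    nxt <- if (i < length(chars)) chars[i + 1L] else ""
    prv <- if (i > 1L) chars[i - 1L] else ""
    if (nxt == "=") next                      # ==
    if (prv %in% c("=", "<", ">", "!")) next  # ==, <=, >=, !=
    op <- "="
    lhs_end <- i - 1L
    if (prv %in% c("+", "-", "*", "/")) {
      op <- paste0(prv, "=")
      lhs_end <- i - 2L
    }
    return(list(lhs = trimws(substr(body, 1L, lhs_end)),
                op = op,
                rhs = trimws(substr(body, i + 1L, nchar(body)))))
  }
  NULL
}

# Replace derivative tokens dX/dt by the internal symbol .grad_X.
# Rejects second-order derivatives.
dsl_replace_derivs <- function(s) {
  if (grepl("d2[A-Za-z_]|d\\^2|/\\s*dt\\s*\\^|/\\s*dt2", s)) {
    stop("only first-order derivatives are supported: ", s, call. = FALSE)
  }
  gsub("(?<![A-Za-z0-9_.])d([A-Za-z_][A-Za-z0-9_]*)\\s*/\\s*dt(?![A-Za-z0-9_])",
       ".grad_\\1", s, perl = TRUE)
}

# Word operators and boolean literals -> R equivalents.
dsl_words_to_ops <- function(s) {
  s <- gsub("(?<![\\w.])and(?![\\w.])", "&", s, perl = TRUE)
  s <- gsub("(?<![\\w.])or(?![\\w.])", "|", s, perl = TRUE)
  s <- gsub("(?<![\\w.])not(?![\\w.])", "!", s, perl = TRUE)
  s <- gsub("(?<![\\w.])(true|True)(?![\\w.])", "TRUE", s, perl = TRUE)
  s <- gsub("(?<![\\w.])(false|False)(?![\\w.])", "FALSE", s, perl = TRUE)
  s
}

# Rewrite Python-style conditionals `if c: a else: b` (possibly nested, and
# possibly embedded in a larger expression) into `.ite(c, a, b)` calls.
dsl_transform_ite <- function(s) {
  m <- regexpr("(?<![\\w.])if(?![\\w.])", s, perl = TRUE)
  if (m == -1L) return(s)
  i <- as.integer(m)
  prefix <- substr(s, 1L, i - 1L)
  rest <- substr(s, i + 2L, nchar(s))
  chars <- strsplit(rest, "")[[1]]
  n <- length(chars)

  tok_at <- function(pos, word) {
    nw <- nchar(word)
    if (pos + nw - 1L > n) return(FALSE)
    if (paste0(chars[pos:(pos + nw - 1L)], collapse = "") != word) return(FALSE)
    before <- if (pos == 1L) "" else chars[pos - 1L]
    after <- if (pos + nw - 1L == n) "" else chars[pos + nw]
    !grepl("[A-Za-z0-9_.]", before) && !grepl("[A-Za-z0-9_.]", after)
  }

  depth <- 0L
  pending <- 0L
  cond_end <- NA_integer_
  else_pos <- NA_integer_
  else_colon <- NA_integer_
  term <- n + 1L
  phase <- "cond"
  j <- 1L
  while (j <= n) {
    ch <- chars[j]
    if (ch %in% c("(", "[")) {
      depth <- depth + 1L
    } else if (ch %in% c(")", "]")) {
      if (depth == 0L) { term <- j; break }
      depth <- depth - 1L
    } else if (depth == 0L) {
      if (ch == ",") { term <- j; break }
      if (phase == "cond" && ch == ":") {
        cond_end <- j; phase <- "then"; j <- j + 1L; next
      }
      if (phase == "then" && tok_at(j, "if")) {
        pending <- pending + 1L; j <- j + 2L; next
      }
      if (phase == "then" && tok_at(j, "else")) {
        if (pending > 0L) { pending <- pending - 1L; j <- j + 4L; next }
        else_pos <- j; phase <- "elsekw"; j <- j + 4L; next
      }
      if (phase == "elsekw" && ch == ":") {
        else_colon <- j; phase <- "else"; j <- j + 1L; next
      }
    }
    j <- j + 1L
  }
  if (is.na(cond_end) || is.na(else_pos) || is.na(else_colon)) {
    stop("malformed conditional in: ", s, call. = FALSE)
  }
  cond <- substr(rest, 1L, cond_end - 1L)
  yes <- substr(rest, cond_end + 1L, else_pos - 1L)
  no <- substr(rest, else_colon + 1L, term - 1L)
  suffix <- if (term <= n) substr(rest, term, n) else ""
  paste0(prefix, ".ite(", dsl_transform_ite(cond), ", ",
         dsl_transform_ite(yes), ", ", dsl_transform_ite(no), ")",
         dsl_transform_ite(suffix))
}

# Full pipeline: DSL expression text -> R language object.
dsl_str2lang <- function(s) {
  s2 <- dsl_transform_ite(dsl_words_to_ops(s))
  out <- tryCatch(str2lang(s2), error = function(e) {
    stop("cannot parse expression: ", s, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  out
}

# Substitute named symbols in a language object.
dsl_substitute <- function(expr, bindings) {
  do.call(substitute, list(expr, bindings))
}

# Canonical textual rendering of an expression tree; inverse of dsl_str2lang
# for the constructs the DSL supports (used for model serialization).
dsl_deparse <- function(e) {
  if (is.symbol(e) || is.atomic(e)) return(deparse1(e))
  if (is.call(e)) {
    head <- e[[1]]
    op <- if (is.symbol(head)) as.character(head) else deparse1(head)
    if (op == ".ite") {
      return(paste0("if ", dsl_deparse(e[[2]]), ": ", dsl_deparse(e[[3]]),
                    " else: ", dsl_deparse(e[[4]])))
    }
    if (op == "(") return(paste0("(", dsl_deparse(e[[2]]), ")"))
    if (op %in% c("+", "-", "*", "/", "^", "<", ">", "<=", ">=",
                  "==", "!=", "&", "|") && length(e) == 3L) {
      return(paste0(dsl_deparse(e[[2]]), " ", op, " ", dsl_deparse(e[[3]])))
    }
    if (op %in% c("+", "-", "!") && length(e) == 2L) {
      return(paste0(op, dsl_deparse(e[[2]])))
    }
    args <- vapply(as.list(e)[-1L], dsl_deparse, character(1))
    return(paste0(op, "(", paste(args, collapse = ", "), ")"))
  }
  deparse1(e)
}

# Numeric value of a flag (init, min, max, proba, w, d ...).
dsl_flag_number <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  v <- flags[[key]]
  if (isTRUE(v)) stop("flag '", key, "' requires a value", call. = FALSE)
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) stop("flag '", key, "' is not numeric: ", v, call. = FALSE)
  num
}
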