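EXPR_FUNCTIONS <- c("norm", "log1p", "gaussian", "rescale", "where",
                    "min", "max", "sum", "mean")

#' Parse a map-calculator expression
#'
#' Parses the pre-processing mini-language used to derive model-ready layers
#' from raw layers: layer identifiers, numeric literals, infix arithmetic
#' (`+ - * /`), comparisons (`< <= > >= == !=`, yielding 0/1 mask layers)
#' and a fixed whitelist of functions:
#'
#' * `norm(x)` — divide by the layer maximum ([normalize_layer()])
#' * `log1p(x)` — logarithmic scaling ([log_scale()])
#' * `gaussian(x, d)` — Gaussian smoothing with propagation distance `d`
#'   meters ([gaussian_convolve()])
#' * `rescale(x, lo, hi)` — affine rescale of the value range
#' * `where(cond, a, b)` — cellwise selection
#' * `min, max, sum, mean` — cellwise aggregation over two or more layers
#'
#' Nothing outside this grammar is representable: parsing is a pure
#' syntactic operation, evaluation is a tree walk, and no host-language
#' evaluation of the source text ever occurs, so expressions from untrusted
#' case-study files are safe. Identifiers may contain hyphens
#' (`[A-Za-z_][A-Za-z0-9_-]*`); consequently subtraction between two named
#' layers must be written with spaces (`a - b`), since `a-b` reads as one
#' identifier. The unicode operators `× ÷ ≤ ≥ ≠` are accepted as synonyms.
#'
#' @param text expression source, non-empty.
#' @return an object of class `msp_expression` with fields `source_text` and
#'   `tree`.
#' @examples
#' parse_expression("norm(log1p(u_transport))")
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("expression text must be a non-empty string")
  src <- text
  text <- chartr("×÷", "*/", text)
  text <- gsub("≤", "<=", text)
  text <- gsub("≥", ">=", text)
  text <- gsub("≠", "!=", text)
  tokens <- tokenize_expression(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$pos <- 1L; st$src <- text
  tree <- parse_comparison(st)
  tk <- peek_token(st)
  if (tk$type != "eof")
    stop("unexpected '", tk$text, "' at offset ", tk$offset, " in expression")
  structure(list(source_text = src, tree = tree), class = "msp_expression")
}

tokenize_expression <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  i <- 1L
  tokens <- list()
  push <- function(type, txt, off)
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = txt,
                                           offset = off)
  is_ident_char <- function(ch) grepl("[A-Za-z0-9_]", ch)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    start <- i
    if (grepl("[A-Za-z_]", ch)) {
      j <- i + 1L
      repeat {
        if (j <= n && is_ident_char(chars[j])) { j <- j + 1L; next }
        # hyphen continues the identifier only when glued to another
        # identifier character (layer codes like "u-fishing")
        if (j < n && chars[j] == "-" && is_ident_char(chars[j + 1L])) {
          j <- j + 2L; next
        }
        break
      }
      push("ident", paste(chars[i:(j - 1L)], collapse = ""), start)
      i <- j
    } else if (grepl("[0-9.]", ch)) {
      j <- i
      while (j <= n && grepl("[0-9.]", chars[j])) j <- j + 1L
      if (j <= n && grepl("[eE]", chars[j])) {
        k <- j + 1L
        if (k <= n && grepl("[+-]", chars[k])) k <- k + 1L
        if (k <= n && grepl("[0-9]", chars[k])) {
          j <- k
          while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
        }
      }
      num <- paste(chars[i:(j - 1L)], collapse = "")
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val)) stop("malformed number '", num, "' at offset ", start)
      push("number", num, start)
      i <- j
    } else if (ch %in% c("<", ">", "!", "=")) {
      if (i < n && chars[i + 1L] == "=") {
        push("cmp", paste0(ch, "="), start); i <- i + 2L
      } else if (ch == "!") {
        stop("unexpected '!' at offset ", start)
      } else if (ch == "=") {
        push("cmp", "==", start); i <- i + 1L  # single '=' means equality
      } else {
        push("cmp", ch, start); i <- i + 1L
      }
    } else if (ch %in% c("+", "-")) {
      push("addop", ch, start); i <- i + 1L
    } else if (ch %in% c("*", "/")) {
      push("mulop", ch, start); i <- i + 1L
    } else if (ch == "(") { push("lparen", ch, start); i <- i + 1L
    } else if (ch == ")") { push("rparen", ch, start); i <- i + 1L
    } else if (ch == ",") { push("comma", ch, start); i <- i + 1L
    } else stop("unexpected character '", ch, "' at offset ", start)
  }
  push("eof", "", n + 1L)
  tokens
}

peek_token <- function(st) st$tokens[[st$pos]]
next_token <- function(st) { tk <- st$tokens[[st$pos]]; st$pos <- st$pos + 1L; tk }
expect_token <- function(st, type, what) {
  tk <- next_token(st)
  if (tk$type != type)
    stop("expected ", what, " at offset ", tk$offset, ", found '",
         if (tk$type == "eof") "end of expression" else tk$text, "'")
  tk
}

parse_comparison <- function(st) {
  lhs <- parse_additive(st)
  while (peek_token(st)$type == "cmp") {
    op <- next_token(st)$text
    rhs <- parse_additive(st)
    lhs <- list(kind = "binop", op = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_additive <- function(st) {
  lhs <- parse_multiplicative(st)
  while (peek_token(st)$type == "addop") {
    op <- next_token(st)$text
    rhs <- parse_multiplicative(st)
    lhs <- list(kind = "binop", op = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_multiplicative <- function(st) {
  lhs <- parse_unary(st)
  while (peek_token(st)$type == "mulop") {
    op <- next_token(st)$text
    rhs <- parse_unary(st)
    lhs <- list(kind = "binop", op = op, lhs = lhs, rhs = rhs)
  }
  lhs
}

parse_unary <- function(st) {
  tk <- peek_token(st)
  if (tk$type == "addop" && tk$text == "-") {
    next_token(st)
    return(list(kind = "neg", arg = parse_unary(st)))
  }
  if (tk$type == "addop" && tk$text == "+") {
    next_token(st)
    return(parse_unary(st))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tk <- next_token(st)
  if (tk$type == "number")
    return(list(kind = "num", value = as.numeric(tk$text)))
  if (tk$type == "lparen") {
    inner <- parse_comparison(st)
    expect_token(st, "rparen", "')'")
    return(inner)
  }
  if (tk$type == "ident") {
    if (peek_token(st)$type == "lparen") {
      if (!(tk$text %in% EXPR_FUNCTIONS))
        stop("unknown function '", tk$text, "' at offset ", tk$offset,
             "; allowed: ", paste(EXPR_FUNCTIONS, collapse = ", "))
      next_token(st)  # consume '('
      args <- list()
      if (peek_token(st)$type != "rparen") {
        repeat {
          args[[length(args) + 1L]] <- parse_comparison(st)
          if (peek_token(st)$type == "comma") { next_token(st); next }
          break
        }
      }
      expect_token(st, "rparen", "')'")
      check_arity(tk$text, length(args), tk$offset)
      return(list(kind = "call", fn = tk$text, args = args))
    }
    return(list(kind = "ident", name = tk$text))
  }
  stop("expected a value at offset ", tk$offset, ", found '",
       if (tk$type == "eof") "end of expression" else tk$text, "'")
}

check_arity <- function(fn, n, offset) {
  ok <- switch(fn,
    norm = , log1p = n == 1L,
    gaussian = n == 2L,
    rescale = n == 3L,
    where = n == 3L,
    min = , max = , sum = , mean = n >= 2L)
  if (!ok)
    stop("function '", fn, "' at offset ", offset,
         " called with ", n, " argument(s)")
  invisible(TRUE)
}

#' @export
format.msp_expression <- function(x, ...) unparse_node(x$tree)

#' @export
print.msp_expression <- function(x, ...) {
  cat("msp_expression:", unparse_node(x$tree), "\n")
  invisible(x)
}

unparse_node <- function(node) {
  switch(node$kind,
    num = format(node$value, digits = 15),
    ident = node$name,
    neg = paste0("(-", unparse_node(node$arg), ")"),
    binop = paste0("(", unparse_node(node$lhs), " ", node$op, " ",
                   unparse_node(node$rhs), ")"),
    call = paste0(node$fn, "(",
                  paste(vapply(node$args, unparse_node, ""), collapse = ", "),
                  ")"),
    stop("unknown node kind '", node$kind, "'"))
}

#' Evaluate a map-calculator expression over a layer registry
#'
#' Walks the parse tree, resolving identifiers in `registry` and delegating
#' whitelisted functions to the corresponding grid operators. Arithmetic and
#' comparisons are cellwise; nodata propagates through them; comparisons
#' yield 0/1 layers so masks compose with arithmetic. Evaluation is purely
#' functional: the same expression and registry always produce the same
#' layer.
#'
#' @param expr an [parse_expression()] result, or expression source text.
#' @param registry named list of aligned [grid_layer()] objects.
#' @param grid grid for purely numeric expressions; defaults to the grid of
#'   the first registry layer.
#' @param name name for the result layer.
#' @return a [grid_layer()].
#' @examples
#' g <- make_grid(c(0, 0, 2000, 2000), 500, "EPSG:3035")
#' a <- grid_layer("a", matrix(1:16, 4, 4), g)
#' evaluate_expression("norm(a) * 2", list(a = a))
#' @export
evaluate_expression <- function(expr, registry, grid = NULL, name = "expr") {
  if (is.character(expr)) expr <- parse_expression(expr)
  if (!inherits(expr, "msp_expression")) stop("expr must be an msp_expression")
  if (is.null(grid)) {
    if (!length(registry)) stop("registry is empty and no grid was given")
    grid <- registry[[1L]]$grid
  }
  for (nm in names(registry)) stopifnot_aligned(registry[[nm]], grid)
  res <- eval_node(expr$tree, registry, grid)
  vals <- if (inherits(res, "grid_layer")) res$values else
    matrix(res, grid$nrow, grid$ncol)
  grid_layer(name, vals, grid)
}

# Nodes evaluate to either a scalar (numeric literal subtrees) or a
# grid_layer; scalars are promoted only when they meet a layer.
eval_node <- function(node, registry, grid) {
  switch(node$kind,
    num = node$value,
    ident = {
      layer <- registry[[node$name]]
      if (is.null(layer))
        stop("unresolved layer identifier '", node$name, "'")
      layer
    },
    neg = {
      v <- eval_node(node$arg, registry, grid)
      if (inherits(v, "grid_layer"))
        grid_layer(v$name, -v$values, grid) else -v
    },
    binop = eval_binop(node, registry, grid),
    call = eval_call(node, registry, grid),
    stop("unknown node kind '", node$kind, "'"))
}

node_values <- function(v) if (inherits(v, "grid_layer")) v$values else v

eval_binop <- function(node, registry, grid) {
  a <- eval_node(node$lhs, registry, grid)
  b <- eval_node(node$rhs, registry, grid)
  av <- node_values(a); bv <- node_values(b)
  out <- switch(node$op,
    "+" = av + bv, "-" = av - bv, "*" = av * bv, "/" = av / bv,
    "<" = as.numeric(av < bv), "<=" = as.numeric(av <= bv),
    ">" = as.numeric(av > bv), ">=" = as.numeric(av >= bv),
    "==" = as.numeric(av == bv), "!=" = as.numeric(av != bv),
    stop("unknown operator '", node$op, "'"))
  if (length(out) == 1L) return(out)
  grid_layer("expr", matrix(out, grid$nrow, grid$ncol), grid)
}

as_layer <- function(v, grid) {
  if (inherits(v, "grid_layer")) v else constant_layer(v, grid)
}

eval_call <- function(node, registry, grid) {
  args <- lapply(node$args, eval_node, registry = registry, grid = grid)
  fn <- node$fn
  if (fn == "norm") return(normalize_layer(as_layer(args[[1L]], grid)))
  if (fn == "log1p") return(log_scale(as_layer(args[[1L]], grid)))
  if (fn == "gaussian") {
    d <- args[[2L]]
    if (inherits(d, "grid_layer"))
      stop("gaussian() distance must be a number, not a layer")
    return(gaussian_convolve(as_layer(args[[1L]], grid), d))
  }
  if (fn == "rescale") {
    lo <- args[[2L]]; hi <- args[[3L]]
    if (inherits(lo, "grid_layer") || inherits(hi, "grid_layer"))
      stop("rescale() bounds must be numbers, not layers")
    return(rescale_layer(as_layer(args[[1L]], grid), lo, hi))
  }
  if (fn == "where") {
    cond <- node_values(as_layer(args[[1L]], grid))
    av <- node_values(args[[2L]]); bv <- node_values(args[[3L]])
    out <- ifelse(is.na(cond), NA_real_,
                  ifelse(cond != 0,
                         av + 0 * cond,  # recycle scalars against the grid
                         bv + 0 * cond))
    return(grid_layer("expr", matrix(out, grid$nrow, grid$ncol), grid))
  }
  mats <- lapply(args, function(a) node_values(as_layer(a, grid)))
  out <- switch(fn,
    min = Reduce(pmin, mats),
    max = Reduce(pmax, mats),
    sum = Reduce(`+`, mats),
    mean = Reduce(`+`, mats) / length(mats),
    stop("unknown function '", fn, "'"))
  grid_layer("expr", out, grid)
}
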