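#' Read and write declarative model files
#'
#' Models can be defined as data rather than code, so a transcription of a
#' published model is reviewable line by line. The format is plain UTF-8
#' key–value text with sections:
#'
#' ```
#' [model]
#' name = toy
#' [states]
#' A = ode
#' B = ode
#' X = implicit_algebraic
#' Y = explicit_algebraic
#' [parameters]
#' k1 = 0          # rates s-1 or uM-1 s-1, concentrations uM
#' [rates]
#' A = k1 - k2 * A         # d(state)/dt for each ode state
#' [algebraic]
#' X ~ k2 * A - k3 * X     # '~' introduces an implicit residual (== 0)
#' Y = 2 * X               # '=' introduces an explicit definition
#' [conserved]
#' Atot = A + X            # total parameter = sum of member states
#' [initial]
#' A = 0
#' ```
#'
#' Lines starting with `#` (or trailing `#` comments) are ignored.
#' Concentrations are in µM and time in s throughout.
#'
#' @param file path to a model file.
#' @return `read_model_file`: a [network_model()].
#' @export
read_model_file <- function(file) {
  if (!file.exists(file)) {
    stop_phaseloop(sprintf("model file not found: %s", file), "phaseloop_io_error")
  }
  raw <- readLines(file, encoding = "UTF-8")
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  section <- NA_character_
  name <- tools::file_path_sans_ext(basename(file))
  kinds <- character()
  params <- numeric()
  init <- numeric()
  rates <- list()
  residuals <- list()
  explicit <- list()
  conserved <- list()
  for (line in raw) {
    if (grepl("^\\[.*\\]$", line)) {
      section <- tolower(gsub("\\[|\\]", "", line))
      next
    }
    if (is.na(section)) {
      stop_phaseloop(sprintf("line outside any section: '%s'", line),
                     "phaseloop_io_error")
    }
    tilde <- section == "algebraic" && grepl("~", line, fixed = TRUE) &&
      (!grepl("=", line, fixed = TRUE) ||
         regexpr("~", line, fixed = TRUE) < regexpr("=", line, fixed = TRUE))
    sep <- if (tilde) "~" else "="
    pos <- regexpr(sep, line, fixed = TRUE)
    if (pos < 0) {
      stop_phaseloop(sprintf("cannot parse line '%s' in section [%s]",
                             line, section),
                     "phaseloop_io_error")
    }
    key <- trimws(substr(line, 1, pos - 1))
    val <- trimws(substr(line, pos + 1, nchar(line)))
    switch(section,
      model = if (key == "name") name <- val,
      states = kinds[key] <- val,
      parameters = params[key] <- as.numeric(val),
      initial = init[key] <- as.numeric(val),
      rates = rates[[key]] <- str2lang(val),
      algebraic = if (tilde) residuals[[key]] <- str2lang(val)
                  else explicit[[key]] <- str2lang(val),
      conserved = conserved[[length(conserved) + 1L]] <-
        list(total = key,
             members = trimws(strsplit(val, "+", fixed = TRUE)[[1]])),
      stop_phaseloop(sprintf("unknown section [%s]", section),
                     "phaseloop_io_error"))
  }
  if (!length(kinds)) {
    stop_phaseloop("model file has no [states] section", "phaseloop_io_error")
  }
  network_model(name = name, states = names(kinds), kind = kinds,
                params = params, rates = rates, residuals = residuals,
                explicit = explicit, conserved = conserved,
                init = if (length(init)) init else NULL)
}

#' @rdname read_model_file
#' @param model a [network_model()].
#' @export
write_model_file <- function(model, file) {
  dep <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = " ")
  lines <- c("[model]", sprintf("name = %s", model$name), "", "[states]",
             sprintf("%s = %s", model$states, model$kind[model$states]))
  if (length(model$params)) {
    lines <- c(lines, "", "[parameters]",
               sprintf("%s = %s", names(model$params), fmt_num(model$params)))
  }
  if (length(model$rates)) {
    lines <- c(lines, "", "[rates]",
               sprintf("%s = %s", names(model$rates),
                       vapply(model$rates, dep, character(1))))
  }
  if (length(model$residuals) || length(model$explicit)) {
    lines <- c(lines, "", "[algebraic]")
    if (length(model$residuals)) {
      lines <- c(lines, sprintf("%s ~ %s", names(model$residuals),
                                vapply(model$residuals, dep, character(1))))
    }
    if (length(model$explicit)) {
      lines <- c(lines, sprintf("%s = %s", names(model$explicit),
                                vapply(model$explicit, dep, character(1))))
    }
  }
  if (length(model$conserved)) {
    lines <- c(lines, "", "[conserved]",
               vapply(model$conserved, function(cc) {
                 sprintf("%s = %s", cc$total, paste(cc$members, collapse = " + "))
               }, character(1)))
  }
  if (!is.null(model$init) && length(model$init)) {
    lines <- c(lines, "", "[initial]",
               sprintf("%s = %s", names(model$init), fmt_num(model$init)))
  }
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

# ---- CellML 1.1 import ----------------------------------------------------

#' Import a CellML 1.1 model
#'
#' A deliberately narrow importer for the subset of CellML 1.1 that plain
#' reaction models use: variables with initial values, and component math
#' consisting of `eq` applications whose left side is either a first-order
#' time derivative (an ode state) or a plain variable (an explicit
#' algebraic state). Connections, unit conversion and events are not
#' interpreted; variable names must be unique across components. Anything
#' outside that subset raises a `phaseloop_cellml_error` recommending the
#' declarative format, so import failures degrade gracefully instead of
#' producing a silently wrong model. Concentrations are assumed to be µM
#' and time s, matching the declarative format.
#'
#' @param file path to a CellML 1.1 file.
#' @param name model name (defaults to the file's model name attribute).
#' @return a [network_model()].
#' @export
import_cellml <- function(file, name = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop_phaseloop("the xml2 package is required for CellML import; use the declarative format instead",
                   "phaseloop_cellml_error")
  }
  fail <- function(msg) {
    stop_phaseloop(paste0("CellML import failed: ", msg,
                          "; transcribe the model to the declarative format (see read_model_file)"),
                   "phaseloop_cellml_error")
  }
  doc <- tryCatch(xml2::read_xml(file), error = function(e) fail(conditionMessage(e)))
  ns <- c(cml = "http://www.cellml.org/cellml/1.1#",
          m = "http://www.w3.org/1998/Math/MathML")
  if (!length(xml2::xml_find_all(doc, "//cml:component", ns))) {
    ns["cml"] <- "http://www.cellml.org/cellml/1.0#"
    if (!length(xml2::xml_find_all(doc, "//cml:component", ns))) {
      fail("no CellML 1.0/1.1 components found")
    }
  }
  if (is.null(name)) {
    name <- xml2::xml_attr(xml2::xml_root(doc), "name")
    if (is.na(name)) name <- tools::file_path_sans_ext(basename(file))
  }
  vars <- xml2::xml_find_all(doc, "//cml:component/cml:variable", ns)
  vnames <- xml2::xml_attr(vars, "name")
  vinit <- suppressWarnings(as.numeric(xml2::xml_attr(vars, "initial_value")))
  if (anyDuplicated(vnames)) {
    dups <- unique(vnames[duplicated(vnames)])
    fail(sprintf("variable name(s) used in more than one component: %s",
                 paste(dups, collapse = ", ")))
  }
  time_var <- "time"
  rates <- list()
  explicit <- list()
  eqs <- xml2::xml_find_all(doc, "//m:math/m:apply", ns)
  for (eq in eqs) {
    kids <- xml2::xml_find_all(eq, "./*[not(self::m:eq)]", ns)
    op <- xml2::xml_name(xml2::xml_child(eq))
    if (op != "eq" || length(kids) != 2) fail("expected top-level <apply><eq/>lhs rhs</apply>")
    lhs <- kids[[1]]
    rhs_expr <- mathml_to_lang(kids[[2]], ns, fail)
    if (xml2::xml_name(lhs) == "apply" &&
        xml2::xml_name(xml2::xml_child(lhs)) == "diff") {
      bvar <- xml2::xml_text(xml2::xml_find_first(lhs, "./m:bvar/m:ci", ns))
      time_var <- trimws(bvar)
      target <- trimws(xml2::xml_text(xml2::xml_find_first(lhs, "./m:ci[not(parent::m:bvar)]", ns)))
      rates[[target]] <- rhs_expr
    } else if (xml2::xml_name(lhs) == "ci") {
      explicit[[trimws(xml2::xml_text(lhs))]] <- rhs_expr
    } else {
      fail(sprintf("unsupported equation left-hand side <%s>", xml2::xml_name(lhs)))
    }
  }
  states <- c(names(rates), names(explicit))
  if (!length(states)) fail("no equations found")
  kinds <- stats::setNames(c(rep("ode", length(rates)),
                             rep("explicit_algebraic", length(explicit))),
                           states)
  pnames <- setdiff(vnames, c(states, time_var))
  params <- stats::setNames(vinit[match(pnames, vnames)], pnames)
  if (anyNA(params)) {
    fail(sprintf("parameter(s) without initial_value: %s",
                 paste(pnames[is.na(params)], collapse = ", ")))
  }
  init <- vinit[match(names(rates), vnames)]
  init[is.na(init)] <- 0
  m <- network_model(name = name, states = states, kind = kinds,
                     params = params, rates = rates, explicit = explicit,
                     init = stats::setNames(init, names(rates)))
  if (time_var != "t") {
    # rewrite any use of the bound time variable to 't'
    m$rates <- lapply(m$rates, rename_symbol, from = time_var, to = "t")
    m$explicit <- lapply(m$explicit, rename_symbol, from = time_var, to = "t")
  }
  m
}

rename_symbol <- function(e, from, to) {
  if (is.name(e) && identical(as.character(e), from)) return(as.name(to))
  if (is.call(e)) {
    for (i in seq_along(e)) if (i > 1 || !is.name(e[[i]])) {
      e[[i]] <- rename_symbol(e[[i]], from, to)
    }
  }
  e
}

# Translate the arithmetic subset of content MathML into an R call tree.
mathml_to_lang <- function(node, ns, fail) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "pi") return(quote(pi))
  if (nm != "apply") fail(sprintf("unsupported MathML node <%s>", nm))
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_lang, ns = ns, fail = fail)
  binop <- function(sym) {
    if (length(args) == 1 && sym == "-") return(call("-", args[[1]]))
    Reduce(function(l, r) call(sym, l, r), args)
  }
  switch(op,
    plus = binop("+"),
    minus = binop("-"),
    times = binop("*"),
    divide = binop("/"),
    power = binop("^"),
    exp = call("exp", args[[1]]),
    ln = call("log", args[[1]]),
    root = call("sqrt", args[[1]]),
    fail(sprintf("unsupported MathML operator <%s>", op)))
}
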