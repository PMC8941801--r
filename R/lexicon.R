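#' Clinical term lexicon for the synthetic corpus generator
#'
#' Per-entity-type term pools. Each type has a `train` pool (terms the
#' training split draws from) and a disjoint `heldout` pool used to emulate
#' out-of-vocabulary mentions in test documents. The pools are seeded from
#' clinical surface forms typical of neurosurgical (pituitary adenoma)
#' admission notes: Cushingoid symptoms such as centripetal obesity
#' (向心性肥胖), buffalo hump (水牛背) and thin skin (皮肤菲薄), body
#' regions such as the lower limbs (双下肢) and sclera (巩膜), comorbid
#' diseases (高血压, 糖尿病, 肝硬化, 微腺瘤), operations
#' (开腹胆囊切除术), medications (溴隐亭), and disease-course phrases
#' (隐匿起病, 慢性病程).
#'
#' The seven pools are pairwise disjoint across entity types so that the
#' synthetic task has a single correct type per surface form; real corpora
#' are more ambiguous (see the package vignette).
#'
#' @return a `lexicon`: named list (one element per entity type), each a
#'   list with character vectors `train` and `heldout`.
#' @export
default_lexicon <- function() {
  lex <- list(
    symptom = list(
      train = c("向心性肥胖", "皮肤菲薄", "水肿", "水牛背", "皮肤发红",
                "锁骨上脂肪垫", "黄染", "腹膨隆", "头晕", "头痛", "恶心",
                "呕吐", "视力下降", "视野缺损", "月经紊乱", "乏力", "紫纹",
                "满月脸", "耳鸣", "发热", "心悸", "泌乳", "多饮多尿",
                "体重增加"),
      heldout = c("凹陷性水肿", "跳痛", "胀痛", "痤疮", "声音嘶哑",
                  "畏寒", "嗜睡", "多毛")
    ),
    body = list(
      train = c("双下肢", "巩膜", "腹部", "颈部", "颞侧", "双侧",
                "大腿内侧", "头部", "双眼", "腰部", "手指关节", "左侧肢体"),
      heldout = c("双上肢", "右眼", "额部", "面部")
    ),
    disease = list(
      train = c("高血压", "糖尿病", "肝硬化", "双肾结石", "左肾囊肿",
                "微腺瘤", "双侧肾上腺增粗", "垂体腺瘤", "鞍区占位",
                "高脂血症", "垂体瘤", "甲状腺功能减退", "库欣综合征",
                "泌乳素瘤", "蝶窦炎"),
      heldout = c("垂体大腺瘤", "空泡蝶鞍", "慢性胃炎", "脂肪肝",
                  "肾功能不全")
    ),
    family = list(
      train = c("肺癌", "胃癌", "乳腺癌", "冠心病", "脑梗死", "心脏病",
                "白血病", "哮喘"),
      heldout = c("肝癌", "食管癌", "帕金森病")
    ),
    surgery = list(
      train = c("开腹胆囊切除术", "经蝶垂体瘤切除术", "阑尾切除术",
                "剖宫产术", "甲状腺切除术", "疝修补术", "骨折内固定术",
                "扁桃体切除术"),
      heldout = c("胆囊切除术", "鼻中隔矫正术", "椎间盘切除术")
    ),
    medication = list(
      train = c("溴隐亭", "阿司匹林", "富马酸比索洛尔", "地塞米松",
                "优甲乐", "利血平", "二甲双胍", "硝苯地平", "泼尼松",
                "卡麦角林"),
      heldout = c("吲达帕胺", "左甲状腺素钠", "美托洛尔", "氢化可的松")
    ),
    progress = list(
      train = c("隐匿起病", "慢性病程", "急性起病", "病程2年", "病程半年",
                "反复发作"),
      heldout = c("亚急性起病", "病程3月", "进行性加重")
    )
  )
  structure(lex, class = "lexicon")
}

#' Validate a lexicon
#'
#' Checks that every term is non-empty, that the train and held-out pools of
#' each type are disjoint, and that no pool holds duplicate entries.
#'
#' @param lex a lexicon as returned by [default_lexicon()].
#' @return `lex`, invisibly.
#' @export
validate_lexicon <- function(lex) {
  for (ty in names(lex)) {
    tr <- lex[[ty]]$train; ho <- lex[[ty]]$heldout
    if (any(!nzchar(c(tr, ho)))) stop_fmt("lexicon[%s]: empty term", ty)
    if (anyDuplicated(tr) || anyDuplicated(ho)) {
      stop_fmt("lexicon[%s]: duplicate entries within a pool", ty)
    }
    if (length(intersect(tr, ho))) {
      stop_fmt("lexicon[%s]: train and heldout pools overlap (%s)",
               ty, paste(intersect(tr, ho), collapse = ", "))
    }
  }
  invisible(lex)
}

#' Lexicon TSV I/O
#'
#' Three tab-separated columns: term, entity type, pool (`train` or
#' `heldout`); UTF-8, no header.
#'
#' @param lex a lexicon.
#' @param path file path.
#' @return `read_lexicon_tsv()`: a lexicon.
#' @export
write_lexicon_tsv <- function(lex, path) {
  rows <- unlist(lapply(names(lex), function(ty) {
    c(paste(lex[[ty]]$train, ty, "train", sep = "\t"),
      paste(lex[[ty]]$heldout, ty, "heldout", sep = "\t"))
  }))
  writeLines(rows, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  lines <- sub("\r$", "", readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop_fmt("lexicon TSV line %d is not 3 columns", bad[1L])
  term <- vapply(parts, `[[`, character(1), 1L)
  type <- vapply(parts, `[[`, character(1), 2L)
  pool <- vapply(parts, `[[`, character(1), 3L)
  lex <- lapply(split(seq_along(term), type), function(idx) {
    list(train = term[idx][pool[idx] == "train"],
         heldout = term[idx][pool[idx] == "heldout"])
  })
  validate_lexicon(structure(lex, class = "lexicon"))
  structure(lex, class = "lexicon")
}
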