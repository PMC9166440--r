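# Findings rules: two-group span queries pairing a hedge/assertion term
# with a disease term within a 10-token window; a span is discarded when
# "no" or "not" occurs within the same window, so negated statements
# ("no findings concerning for recurrence") are excluded. The suspicious
# rule is listed first: a report firing both is surfaced as a conflict and
# labelled suspicious.
axis: findings
default: null
suspicious: SPAN(groups=[suspicious|worrisome|concerning, recurrence|recurrent|metastasis|metastatic|metastases]; window=10; not=[no,not]; ordered=false; scope=match)
recurrence: SPAN(groups=[consistent|definite|definitive|diagnostic|compatible, recurrence|recurrent|metastasis|metastatic|metastases]; window=10; not=[no,not]; ordered=false; scope=match)
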