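# Indication rules. Only the surveillance indication has a retrieval rule;
# every other report falls through to the default label and is left for
# manual review. Editable approximation of surveillance phrasing.
axis: indication
default: unknown
surveillance: OR(surveillance; "surveillance imaging"; "interval surveillance")
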