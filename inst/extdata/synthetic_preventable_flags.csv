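code_prefix,setting
643.0,ED
300.0,ED
305.0,ED
345.9,ED
250.1,ED
401.9,ED
493.90,ED
724.5,ED
558.9,ED
599.0,ED
965.0,ED
780.60,ED
799.01,ED
646.6,IP
296.8,IP
303.9,IP
348.1,IP
250.8,IP
428.0,IP
493.91,IP
714.0,IP
530.1,IP
590.80,IP
850.0,IP
780.97,IP
799.02,IP
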