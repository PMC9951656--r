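code,category
111,urban
112,urban
121,urban
122,urban
123,urban
124,urban
131,urban
132,urban
133,urban
141,urban
142,urban
211,rural
212,rural
213,rural
221,rural
222,rural
223,rural
231,rural
241,rural
242,rural
243,rural
244,rural
311,rural
312,rural
313,rural
321,rural
322,rural
323,rural
324,rural
331,rural
332,rural
333,rural
334,rural
335,rural
411,rural
412,rural
421,rural
422,rural
423,rural
511,rural
512,rural
521,rural
522,rural
523,rural
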