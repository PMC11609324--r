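network	label	x	y	z
ERN1	L superior frontal gyrus	-20	32	44
ERN1	L middle frontal gyrus	-40	26	34
ERN1	R middle frontal gyrus	42	28	34
ERN1	R middle frontal gyrus posterior	40	6	52
ERN1	L inferior parietal lobule	-44	-48	44
ERN1	R inferior parietal lobule	46	-46	44
ERN1	R insula	38	18	2
ERN1	cingulate gyrus	2	20	38
ERN1	precuneus	-2	-62	46
ERN2	L inferior frontal gyrus	-48	24	8
ERN2	R inferior frontal gyrus	50	26	6
ERN2	L superior frontal gyrus medial	-6	52	30
ERN2	L superior temporal gyrus	-54	-40	10
ERN2	L middle frontal gyrus	-38	44	16
ERN2	L middle temporal gyrus	-56	-36	-4
ERN2	L caudate	-10	10	6
ERN2	R tuber	34	-62	-30
ERN2	L inferior frontal gyrus orbital	-44	30	-10
ERN3	L amygdala	-22	-4	-18
ERN3	R amygdala	24	-2	-18
ERN3	L fusiform gyrus	-40	-52	-18
ERN3	R fusiform gyrus	42	-50	-18
ERN3	medial prefrontal gyrus	2	48	-8
ERN3	R thalamus	10	-18	8
ERN3	L parahippocampal gyrus	-26	-34	-14
ERN3	L inferior occipital gyrus	-40	-82	-10
ERN4	L postcentral gyrus	-44	-26	50
ERN4	R postcentral gyrus	46	-24	50
ERN4	L insula	-38	-6	8
ERN4	L superior parietal lobule	-28	-54	60
ERN4	L cuneus	-8	-80	28
ERN4	L middle occipital gyrus	-32	-84	16
ERN4	R thalamus	12	-20	4
ERN4	R precuneus	10	-58	42
ERN4	R posterior cingulate	6	-44	24
ERN4	L postcentral gyrus inferior	-56	-22	34
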