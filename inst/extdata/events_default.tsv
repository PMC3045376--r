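onset	duration	trial_type
0	15	neutral
15	15	strategic
30	15	strategic
45	15	neutral
60	15	justice
75	15	justice
90	15	neutral
105	15	strategic
120	15	strategic
135	15	neutral
150	15	care
165	15	care
180	15	neutral
195	15	care
210	15	care
225	15	neutral
240	15	neutral
255	15	justice
270	15	justice
285	15	neutral
300	15	care
315	15	care
330	15	neutral
345	15	strategic
360	15	strategic
375	15	neutral
390	15	neutral
405	15	justice
420	15	justice
435	15	neutral
450	15	neutral
465	15	tactical
480	15	tactical
495	15	neutral
510	15	tactical
525	15	tactical
540	15	neutral
555	15	neutral
570	15	tactical
585	15	tactical
600	15	neutral
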