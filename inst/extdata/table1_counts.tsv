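dx1	dx2	realized	potential
MDE	MDE	93	136
Dys	Dys	34	45
Man	Man	40	45
GAD	GAD	28	28
Soc	Soc	9	10
Spe	Spe	10	10
Pan	Pan	6	6
Ago	Ago	6	6
PTSD	PTSD	129	171
ADHD	ADHD	99	153
Alc	Alc	57	78
Nic	Nic	21	21
Dys	MDE	10	170
Man	MDE	15	170
Man	Dys	0	100
GAD	MDE	8	136
GAD	Dys	2	80
GAD	Man	2	80
Soc	MDE	7	85
Soc	Dys	0	50
Soc	Man	3	50
Soc	GAD	1	40
Spe	MDE	5	85
Spe	Dys	0	50
Spe	Man	1	50
Spe	GAD	0	40
Spe	Soc	4	25
Pan	MDE	8	68
Pan	Dys	1	40
Pan	Man	2	40
Pan	GAD	0	32
Pan	Soc	3	20
Pan	Spe	1	20
Ago	MDE	0	68
Ago	Dys	0	40
Ago	Man	0	40
Ago	GAD	0	32
Ago	Soc	4	20
Ago	Spe	5	20
Ago	Pan	9	16
PTSD	MDE	11	323
PTSD	Dys	0	190
PTSD	Man	4	190
PTSD	GAD	2	152
PTSD	Soc	1	95
PTSD	Spe	15	95
PTSD	Pan	5	76
PTSD	Ago	0	76
ADHD	MDE	5	306
ADHD	Dys	0	180
ADHD	Man	10	180
ADHD	GAD	1	144
ADHD	Soc	1	90
ADHD	Spe	10	90
ADHD	Pan	1	72
ADHD	Ago	0	72
ADHD	PTSD	20	342
Alc	MDE	3	221
Alc	Dys	0	130
Alc	Man	2	130
Alc	GAD	0	104
Alc	Soc	0	65
Alc	Spe	1	65
Alc	Pan	2	52
Alc	Ago	0	52
Alc	PTSD	3	247
Alc	ADHD	5	234
Nic	MDE	3	119
Nic	Dys	0	70
Nic	Man	1	70
Nic	GAD	0	56
Nic	Soc	1	35
Nic	Spe	3	35
Nic	Pan	1	28
Nic	Ago	0	28
Nic	PTSD	5	133
Nic	ADHD	8	126
Nic	Alc	9	91
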