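# Published per-interviewer novelty counts from a whole-population Chacobo
# plant-use freelist survey: distinct items ("unique") and (interview, item)
# incidences ("mentions") elicited by each interviewer that were absent from
# ("novel") or present in ("same") the interviewer's own reported knowledge.
# group: similar = interviewers who tended to elicit answers similar to
# their own; different = least similar.
interviewer	group	item_class	status	unique	mentions
BCM	similar	species	novel	84	1193
BCM	similar	species	same	57	2866
BCM	similar	use	novel	27	4059
BCM	similar	use	same	22	3895
BCM	similar	plant_use	novel	216	2030
BCM	similar	plant_use	same	58	2029
MOV	similar	species	novel	102	710
MOV	similar	species	same	46	1719
MOV	similar	use	novel	34	2429
MOV	similar	use	same	16	2181
MOV	similar	plant_use	novel	282	1372
MOV	similar	plant_use	same	52	1057
SCO	similar	species	novel	106	1206
SCO	similar	species	same	48	1697
SCO	similar	use	novel	29	2903
SCO	similar	use	same	20	2779
SCO	similar	plant_use	novel	233	1541
SCO	similar	plant_use	same	52	1362
GCM	different	species	novel	93	686
GCM	different	species	same	49	1420
GCM	different	use	novel	33	2106
GCM	different	use	same	25	2026
GCM	different	plant_use	novel	252	1095
GCM	different	plant_use	same	60	1011
MSM	different	species	novel	104	722
MSM	different	species	same	49	1061
MSM	different	use	novel	29	1783
MSM	different	use	same	23	1570
MSM	different	plant_use	novel	266	1225
MSM	different	plant_use	same	48	558
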