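sample_id	age	apc_mutation	exposure	diagnosis	surgery
II.1	41	Absent	None		
III.1	9	Absent	None		
III.2	16	Absent	None		
III.3	52	Present (Het)	tobacco chewing	FAP, Oral Cancer	Yes
III.4	54	Present (Het)	Pan masala with tobacco	FAP	Yes
III.5	44	Present (Het)	Pan masala with tobacco	FAP	
III.7	60	Present (Het)	None	FAP	Yes
IV.1	21	Absent	Pan masala with tobacco		
IV.2	23	Present (Het)	None		
IV.3	17	Absent	None		
IV.4	23	Absent	None		
IV.5	18	Absent	None		
IV.6	18	Present (Het)	None		
IV.7	28	Absent	None		
IV.8	35	Present (Het)	Smoking cigarette	FAP	Yes
IV.9	27	Absent	None		
IV.10	31	Absent	None		
IV.11	34	Absent	None		
IV.12	38	Present (Het)	Pan masala with tobacco/ chewing tobacco	FAP	Yes
IV.13	36	Absent	Smoking cigarette		
V.1	4	Absent	None		
V.2	4	Absent	None		
V.3	8	Present (Het)	None		
V.5	12	Absent	None		
V.6	6	Present (Het)	None		
V.7	9	Absent	None		
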