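class	template	kind
# patient, actual use: first-person family, usage verb adjacent to the slot
pt	my son is on {TREATMENT} now.	plain
pt	we started {TREATMENT} last month.	plain
pt	my daughter takes {TREATMENT} every day.	plain
pt	our son gets {TREATMENT} twice a week.	plain
pt	my kid stayed calmer after we began {TREATMENT} this spring.	plain
# patient, no actual use indicated: suggestion / consideration cues
pt-gen	the doctor suggested {TREATMENT} for my son.	plain
pt-gen	we are considering {TREATMENT} for our daughter.	plain
pt-gen	the pediatrician recommended {TREATMENT} at our last visit.	plain
pt-gen	they want to prescribe {TREATMENT} for my son.	plain
# caregiver: the posting parent herself
cg	i take {TREATMENT} myself for stress.	plain
cg	i started taking {TREATMENT} myself last year.	plain
cg	i rely on {TREATMENT} for my own anxiety.	plain
# others: specific individuals who are not the author or the patient
others	her daughter tried {TREATMENT} last year.	plain
others	another mom gave her kid {TREATMENT} recently.	plain
others	his teacher swears by {TREATMENT} for focus.	plain
# generic: not tied to anyone specific
gen	{TREATMENT} has no scientific evidence behind it.	plain
gen	there are many studies about {TREATMENT} online.	plain
gen	everyone keeps debating {TREATMENT} in this forum.	plain
gen	i read an article describing {TREATMENT} yesterday.	plain
# sentences without any treatment mention
none	our appointment went well today.	plain
none	thanks so much for all the support here.	plain
none	we had a rough night again.	plain
none	the school meeting is set for next week.	plain
none	hope everyone is hanging in there.	plain
# ambiguous cues shared between class pairs: the surface underdetermines the label
pt-gen	we talked about {TREATMENT} at our appointment.	ambiguous
gen	we talked about {TREATMENT} at our appointment.	ambiguous
pt-gen	someone mentioned {TREATMENT} to us again.	ambiguous
gen	someone mentioned {TREATMENT} to us again.	ambiguous
pt	our plan still includes {TREATMENT} somehow.	ambiguous
pt-gen	our plan still includes {TREATMENT} somehow.	ambiguous
others	people around here mention {TREATMENT} a lot.	ambiguous
gen	people around here mention {TREATMENT} a lot.	ambiguous
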