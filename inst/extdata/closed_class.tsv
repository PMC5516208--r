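word	pos
# pronouns
i	PRON
me	PRON
my	PRON
mine	PRON
myself	PRON
we	PRON
us	PRON
our	PRON
ours	PRON
ourselves	PRON
you	PRON
your	PRON
yours	PRON
yourself	PRON
he	PRON
him	PRON
his	PRON
himself	PRON
she	PRON
her	PRON
hers	PRON
herself	PRON
it	PRON
its	PRON
itself	PRON
they	PRON
them	PRON
their	PRON
theirs	PRON
themselves	PRON
who	PRON
whom	PRON
whose	PRON
someone	PRON
anyone	PRON
everyone	PRON
nobody	PRON
somebody	PRON
anybody	PRON
everybody	PRON
something	PRON
anything	PRON
everything	PRON
nothing	PRON
# determiners
the	DET
a	DET
an	DET
this	DET
that	DET
these	DET
those	DET
each	DET
every	DET
either	DET
neither	DET
some	DET
any	DET
no	DET
all	DET
both	DET
few	DET
several	DET
many	DET
much	DET
most	DET
other	DET
another	DET
such	DET
what	DET
which	DET
# prepositions / particles
of	ADP
in	ADP
on	ADP
at	ADP
by	ADP
for	ADP
with	ADP
without	ADP
about	ADP
against	ADP
between	ADP
into	ADP
through	ADP
during	ADP
before	ADP
after	ADP
above	ADP
below	ADP
to	ADP
from	ADP
up	ADP
down	ADP
out	ADP
off	ADP
over	ADP
under	ADP
again	ADV
since	ADP
until	ADP
around	ADP
among	ADP
within	ADP
across	ADP
behind	ADP
beyond	ADP
near	ADP
onto	ADP
upon	ADP
toward	ADP
towards	ADP
per	ADP
via	ADP
despite	ADP
except	ADP
like	ADP
as	ADP
# auxiliaries and frequent verbs
am	VERB
is	VERB
are	VERB
was	VERB
were	VERB
be	VERB
been	VERB
being	VERB
have	VERB
has	VERB
had	VERB
having	VERB
do	VERB
does	VERB
did	VERB
doing	VERB
will	VERB
would	VERB
shall	VERB
should	VERB
can	VERB
could	VERB
may	VERB
might	VERB
must	VERB
ought	VERB
need	VERB
needs	VERB
take	VERB
takes	VERB
took	VERB
taken	VERB
give	VERB
gives	VERB
gave	VERB
given	VERB
get	VERB
gets	VERB
got	VERB
gotten	VERB
go	VERB
goes	VERB
went	VERB
gone	VERB
put	VERB
puts	VERB
make	VERB
makes	VERB
made	VERB
see	VERB
sees	VERB
saw	VERB
seen	VERB
say	VERB
says	VERB
said	VERB
tell	VERB
tells	VERB
told	VERB
know	VERB
knows	VERB
knew	VERB
known	VERB
think	VERB
thinks	VERB
thought	VERB
try	VERB
tries	VERB
use	VERB
uses	VERB
find	VERB
finds	VERB
found	VERB
keep	VERB
keeps	VERB
kept	VERB
let	VERB
lets	VERB
begin	VERB
begins	VERB
began	VERB
begun	VERB
start	VERB
starts	VERB
stop	VERB
stops	VERB
feel	VERB
feels	VERB
felt	VERB
read	VERB
reads	VERB
hear	VERB
hears	VERB
heard	VERB
write	VERB
writes	VERB
wrote	VERB
written	VERB
come	VERB
comes	VERB
came	VERB
run	VERB
runs	VERB
ran	VERB
help	VERB
helps	VERB
work	VERB
works	VERB
seem	VERB
seems	VERB
want	VERB
wants	VERB
wish	VERB
wishes	VERB
hope	VERB
hopes	VERB
ask	VERB
asks	VERB
mean	VERB
means	VERB
meant	VERB
buy	VERB
buys	VERB
bought	VERB
pay	VERB
pays	VERB
paid	VERB
sleep	VERB
sleeps	VERB
slept	VERB
eat	VERB
eats	VERB
ate	VERB
eaten	VERB
grow	VERB
grows	VERB
grew	VERB
grown	VERB
speak	VERB
speaks	VERB
spoke	VERB
spoken	VERB
# conjunctions and misc function words
and	X
or	X
but	X
nor	X
so	X
yet	X
if	X
because	X
although	X
though	X
while	X
when	X
where	X
why	X
how	X
whether	X
unless	X
than	X
then	ADV
also	ADV
too	ADV
very	ADV
really	ADV
quite	ADV
just	ADV
only	ADV
even	ADV
still	ADV
already	ADV
always	ADV
never	ADV
often	ADV
sometimes	ADV
usually	ADV
now	ADV
soon	ADV
later	ADV
today	ADV
yesterday	ADV
tomorrow	ADV
here	ADV
there	ADV
not	ADV
n't	ADV
maybe	ADV
perhaps	ADV
well	ADV
online	ADV
ever	ADV
once	ADV
twice	ADV
again	ADV
away	ADV
back	ADV
together	ADV
instead	ADV
however	ADV
anyway	ADV
please	ADV
# common adjectives
good	ADJ
bad	ADJ
new	ADJ
old	ADJ
great	ADJ
little	ADJ
big	ADJ
small	ADJ
high	ADJ
low	ADJ
long	ADJ
short	ADJ
own	ADJ
same	ADJ
different	ADJ
young	ADJ
early	ADJ
late	ADJ
hard	ADJ
easy	ADJ
sure	ADJ
happy	ADJ
glad	ADJ
fine	ADJ
best	ADJ
better	ADJ
worse	ADJ
worst	ADJ
last	ADJ
next	ADJ
first	ADJ
second	ADJ
third	ADJ
special	ADJ
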