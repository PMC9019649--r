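# English function words: prepositions, conjunctions, pronouns,
# auxiliaries, determiners. Articles (a, an, the) are listed here too
# but are additionally flagged as articles by the tokenizer.
a
an
the
and
or
but
nor
so
yet
for
of
to
in
on
at
by
with
from
into
onto
over
under
above
below
between
among
through
during
before
after
against
about
as
per
via
within
without
along
across
around
off
out
up
down
near
i
me
my
mine
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
this
that
these
those
who
whom
whose
which
what
be
am
is
are
was
were
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
not
no
if
then
than
because
while
when
where
why
how
there
here
all
any
both
each
few
more
most
other
some
such
only
own
same
too
very
just
also
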